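test_that("randomize_regions preserves widths, respects bounds, is seeded", {
  si <- fixture_genome(c(chr1 = 50000, chr2 = 20000))
  set.seed(51)
  gr <- random_intervals(si, 500, wmin = 10, wmax = 2000)
  r1 <- randomize_regions(gr, seed = 9)
  expect_equal(sort(GenomicRanges::width(r1)), sort(GenomicRanges::width(gr)))
  expect_true(all(GenomicRanges::start(r1) >= 1))
  lens <- GenomeInfoDb::seqlengths(si)[as.character(GenomicRanges::seqnames(r1))]
  expect_true(all(GenomicRanges::end(r1) <= lens))
  r2 <- randomize_regions(gr, seed = 9)
  expect_identical(GenomicRanges::start(r1), GenomicRanges::start(r2))
  r3 <- randomize_regions(gr, seed = 10)
  expect_false(identical(GenomicRanges::start(r1), GenomicRanges::start(r3)))

  wide <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 50000), seqinfo = si)
  expect_error(randomize_regions(wide, genome = fixture_genome(c(s = 100))),
               "wider")
})

test_that("fast null-path counting equals the public overlap counter", {
  set.seed(53)
  si <- fixture_genome(c(chr1 = 30000, chr2 = 15000))
  for (rep in 1:10) {
    q <- random_intervals(si, 150, wmin = 5, wmax = 900)
    f <- random_intervals(si, 80, wmin = 5, wmax = 1500)
    fast <- g4scape:::.fast_counts(as.character(GenomicRanges::seqnames(q)),
                                   GenomicRanges::start(q),
                                   GenomicRanges::end(q),
                                   g4scape:::.feature_index(f))
    expect_equal(fast, count_overlaps(q, f))
  }
})

test_that("a genome-wide feature gives a degenerate, non-significant null", {
  si <- fixture_genome(c(chr1 = 100000))
  set.seed(55)
  peaks <- random_intervals(si, 50, wmin = 100, wmax = 500)
  whole <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100000),
                                  seqinfo = si)
  r <- permutation_enrichment(peaks, whole, n_perm = 99, seed = 3)
  expect_equal(r$observed, 1)
  expect_equal(r$null_mean, 1)
  expect_true(r$degenerate)
  expect_equal(r$z, 0)
  expect_equal(r$p_emp, 1)  # (1 + 99) / (99 + 1): every null draw ties
})

test_that("planted peaks inside sparse features are called enriched", {
  # features cover 5% of a 10-Mb genome; every peak planted inside one
  si <- fixture_genome(c(chr1 = 1e7))
  feat <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1, 1e7 - 5e4, by = 1e6), width = 5e4), seqinfo = si)
  set.seed(57)
  fi <- sample(length(feat), 200, replace = TRUE)
  start <- GenomicRanges::start(feat)[fi] +
    sample(0:(5e4 - 300), 200, replace = TRUE)
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(start, start + 299),
                                  seqinfo = si)
  r <- permutation_enrichment(peaks, feat, n_perm = 1000, seed = 5)
  expect_gt(r$z, 5)
  expect_equal(r$p_emp, 1 / 1001)
})

test_that("z is invariant under chromosome relabeling", {
  si <- fixture_genome(c(chr1 = 40000, chr2 = 40000))
  set.seed(59)
  peaks <- random_intervals(si, 60, wmin = 50, wmax = 400)
  feat <- random_intervals(si, 30, wmin = 200, wmax = 2000)
  relabel <- function(gr) {
    new <- GenomicRanges::GRanges(
      chartr("12", "89", as.character(GenomicRanges::seqnames(gr))),
      IRanges::ranges(gr),
      seqinfo = genome_index(c(chr8 = 40000, chr9 = 40000)))
    new
  }
  r1 <- permutation_enrichment(peaks, feat, n_perm = 200, seed = 11)
  r2 <- permutation_enrichment(relabel(peaks), relabel(feat),
                               n_perm = 200, seed = 11)
  expect_equal(r1$z, r2$z)
  expect_equal(r1$p_emp, r2$p_emp)
})

test_that("multi-feature table shares one null stream across features", {
  si <- fixture_genome(c(chr1 = 2e5))
  set.seed(61)
  peaks <- random_intervals(si, 40, wmin = 100, wmax = 300)
  f <- random_intervals(si, 25, wmin = 200, wmax = 1000)
  tab <- multi_feature_enrichment(peaks, list(one = f, two = f),
                                  n_perm = 150, seed = 13)
  expect_equal(tab[1, -1], tab[2, -1], ignore_attr = TRUE)

  # identical to the single-feature test under the same seed
  single <- permutation_enrichment(peaks, f, n_perm = 150, seed = 13)
  expect_equal(tab$z[1], single$z)
  expect_equal(tab$p_emp[1], single$p_emp)

  empty <- multi_feature_enrichment(peaks, setNames(list(), character(0)),
                                    n_perm = 10, seed = 1)
  expect_equal(nrow(empty), 0)

  # planted signal ranks far above a decoy feature set
  fi <- sample(length(f), 40, replace = TRUE)
  planted <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(GenomicRanges::start(f)[fi], width = 50), seqinfo = si)
  set.seed(62)
  decoy <- random_intervals(si, 25, wmin = 200, wmax = 1000)
  tab2 <- multi_feature_enrichment(planted, list(signal = f, decoy = decoy),
                                   n_perm = 300, seed = 15)
  expect_gt(tab2$z[tab2$feature == "signal"],
            tab2$z[tab2$feature == "decoy"] + 3)
})

test_that("observed statistic shares the public code path (flank 0)", {
  si <- fixture_genome(c(chr1 = 1e5))
  set.seed(63)
  peaks <- random_intervals(si, 30, wmin = 100, wmax = 400)
  feat <- random_intervals(si, 20, wmin = 100, wmax = 1000)
  r <- permutation_enrichment(peaks, feat, statistic = "total_overlap_count",
                              n_perm = 20, seed = 1)
  expect_equal(r$observed, sum(count_overlaps(peaks, feat)))
  r2 <- permutation_enrichment(peaks, feat, n_perm = 20, seed = 1)
  expect_equal(r2$observed, mean(count_overlaps(peaks, feat) > 0))
})
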