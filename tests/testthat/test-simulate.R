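test_that("generated genomes hit the requested lengths, GC and bytes", {
  spec <- sim_spec(chrom_lengths = c(c1 = 1e6), seed = 5)
  g <- make_genome(spec)
  expect_equal(unname(GenomeInfoDb::seqlengths(g$genome)), 1e6)
  freq <- Biostrings::alphabetFrequency(g$sequences[[1]])
  gc <- sum(freq[c("C", "G")]) / 1e6
  expect_lt(abs(gc - 0.41), 0.01)

  again <- make_genome(spec)
  expect_identical(as.character(g$sequences), as.character(again$sequences))
  other <- make_genome(sim_spec(chrom_lengths = c(c1 = 1e6), seed = 6))
  expect_false(identical(as.character(g$sequences),
                         as.character(other$sequences)))
  expect_error(sim_spec(gc_content = 1.4), "fractions")
})

test_that("the synthetic consensus carries exactly three canonical G4s", {
  cons <- l1_consensus()
  expect_equal(nchar(cons), 1200)
  expect_identical(cons, l1_consensus())  # deterministic
  m <- find_g4_motifs(cons, quadparser_preset("canonical"), "both")
  expect_equal(nrow(m), 3)
  expect_true(all(m$strand == "+"))
})

test_that("planted repeats keep motifs when conserved, lose them when degraded", {
  spec <- small_spec(seed = 9)
  g <- make_genome(spec)
  pr <- plant_repeats(g, l1_consensus(), spec)
  rpt <- pr$repeats
  expect_length(rpt, spec$n_repeat_copies)
  expect_equal(sum(rpt$conserved), round(0.4 * spec$n_repeat_copies))
  expect_true(all(rpt$n_motifs_retained[rpt$conserved] == 3))
  expect_true(all(rpt$milli_div[rpt$conserved] == 0))
  # degraded copies lose motifs on average
  expect_lt(mean(rpt$n_motifs_retained[!rpt$conserved]), 3)
  expect_gt(mean(rpt$milli_div[!rpt$conserved]), 100)
  # copies do not overlap each other
  expect_true(all(count_overlaps(rpt, rpt) == 1))
  # planted copies are really in the sequence: re-scan the genome
  track <- genome_g4_track(pr$sequences)
  cons_hits <- count_overlaps(rpt[rpt$conserved], track)
  expect_true(all(cons_hits >= 3))

  # zero divergence keeps everything
  spec0 <- small_spec(seed = 9, divergence_rate = 0)
  pr0 <- plant_repeats(make_genome(spec0), l1_consensus(), spec0)
  expect_true(all(pr0$repeats$n_motifs_retained == 3))
  # heavier divergence degrades more
  spec3 <- small_spec(seed = 9, divergence_rate = 0.3)
  pr3 <- plant_repeats(make_genome(spec3), l1_consensus(), spec3)
  expect_lt(mean(pr3$repeats$n_motifs_retained[!pr3$repeats$conserved]),
            mean(pr0$repeats$n_motifs_retained))
})

test_that("simulated peaks target conserved copies at the stated rate", {
  spec <- small_spec(seed = 13)
  g <- make_genome(spec)
  pr <- plant_repeats(g, l1_consensus(), spec)

  all_on <- simulate_peaks(pr$repeats, small_spec(seed = 13,
                                                  p_peak_on_conserved = 1))
  expect_length(all_on, spec$n_peaks)
  cons <- pr$repeats[pr$repeats$conserved]
  expect_true(all(count_overlaps(all_on, cons) > 0))

  none_on <- simulate_peaks(pr$repeats, small_spec(seed = 13,
                                                   p_peak_on_conserved = 0))
  # background overlap rate ~ repeat coverage broadened by peak width
  frac <- mean(count_overlaps(none_on, pr$repeats) > 0)
  expect_lt(frac, 0.35)
  expect_true(all(none_on$label == "background"))
})

test_that("simulated LAD maps hit target coverage and stay disjoint", {
  spec <- small_spec(lad_coverage = 0.5)
  si <- genome_index(spec$chrom_lengths)
  lads <- simulate_lads(si, spec)
  union <- c(lads$clad, lads$flad)
  expect_lt(abs(coverage_fraction(union, si) - 0.5), 0.02)
  expect_true(all(count_overlaps(lads$clad, lads$flad) == 0))
  # 60/40 split between constitutive and facultative
  share_c <- coverage_fraction(lads$clad, si) / coverage_fraction(union, si)
  expect_lt(abs(share_c - 0.6), 0.1)

  none <- simulate_lads(si, small_spec(lad_coverage = 0))
  expect_length(none$clad, 0)
  expect_length(none$flad, 0)
})

test_that("simulated DE tables carry the baseline and the planted bias", {
  spec <- sim_spec(n_genes = 10000L, seed = 17)
  d <- simulate_de_table(spec)
  expect_equal(nrow(d$de), 10000)
  expect_lt(abs(upregulated_fraction(d$de[!d$de$gene_id %in% d$flagged, ]) -
                0.51), 0.011)
  # flagged genes lean down
  expect_lt(upregulated_fraction(d$de[d$de$gene_id %in% d$flagged, ]), 0.45)
  # gene intervals tile without overlap and are named
  expect_true(all(count_overlaps(d$genes, d$genes) == 1))
  expect_equal(d$genes$name, d$de$gene_id)

  # null planted bias is indistinguishable from background
  null_spec <- sim_spec(n_genes = 10000L, seed = 17, frac_up = 0.5,
                        planted_down_bias = 0.5)
  dn <- simulate_de_table(null_spec)
  r <- direction_binomial_test(dn$flagged, dn$de, baseline_up = 0.5)
  expect_gt(min(r$p_enriched_down, r$p_enriched_up), 0.01)
})

test_that("simulate_study writes a complete, re-readable file bundle", {
  dir <- file.path(tempdir(), "simbundle")
  on.exit(unlink(dir, recursive = TRUE))
  spec <- small_spec(seed = 21)
  st <- simulate_study(spec, dir)
  expect_true(all(file.exists(unlist(st$files))))

  fa <- read_fasta(st$files$genome)
  expect_equal(GenomeInfoDb::seqlengths(fa$genome),
               GenomeInfoDb::seqlengths(st$genome))
  peaks <- read_bed(st$files$peaks_a, fa$genome)
  expect_length(peaks, length(st$peaks_a))
  expect_equal(GenomicRanges::start(peaks), GenomicRanges::start(st$peaks_a))
  rpt <- read_rmsk(st$files$rmsk, fa$genome)
  expect_length(rpt, spec$n_repeat_copies)
  expect_equal(rpt$repeat_family, st$repeats$repeat_family)
  de <- read_de_table(st$files$de)
  expect_equal(de$gene_id, st$de$gene_id)
  truth <- jsonlite::read_json(st$files$truth)
  expect_equal(truth$conserved_copies, sum(st$repeats$conserved))
})
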