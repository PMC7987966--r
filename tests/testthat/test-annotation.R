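rmsk_fixture <- function(si) {
  # BED-like 0-based rows: an L1, an Alu, an LTR element
  df <- data.frame(chrom = "chr1", start = c(100, 300, 700),
                   end = c(250, 380, 900),
                   name = c("L1PA3", "AluSx", "MLT1A"),
                   class = c("LINE", "SINE", "LTR"),
                   family = c("L1", "Alu", "ERVL-MaLR"))
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  read_rmsk(path, si)
}

test_that("read_rmsk accepts both dialects and validates coordinates", {
  si <- fixture_genome(c(chr1 = 10000))
  minimal <- rmsk_fixture(si)
  expect_length(minimal, 3)
  expect_equal(minimal$repeat_class, c("LINE", "SINE", "LTR"))
  expect_equal(GenomicRanges::start(minimal), c(101L, 301L, 701L))

  # UCSC header dialect parses to the same records
  full <- data.frame(bin = 0, swScore = 1000, milliDiv = c(50, 120, 300),
                     genoName = "chr1", genoStart = c(100, 300, 700),
                     genoEnd = c(250, 380, 900), strand = "+",
                     repName = c("L1PA3", "AluSx", "MLT1A"),
                     repClass = c("LINE", "SINE", "LTR"),
                     repFamily = c("L1", "Alu", "ERVL-MaLR"))
  path <- tempfile(fileext = ".tsv")
  write.table(full, path, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_rmsk(path, si)
  expect_equal(GenomicRanges::start(got), GenomicRanges::start(minimal))
  expect_equal(got$repeat_family, minimal$repeat_family)
  expect_equal(got$milli_div, c(50, 120, 300))

  bad <- data.frame(chrom = "chr1", start = 500, end = 400, name = "x",
                    class = "LINE", family = "L1")
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  expect_error(read_rmsk(path, si), "line 1")
})

test_that("repeat profile counts non-exclusive category membership", {
  si <- fixture_genome(c(chr1 = 10000))
  rpt <- rmsk_fixture(si)
  # one peak spanning both the L1 and the Alu, one peak on nothing
  peaks <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(90, 5000), c(400, 5100)),
                                  seqinfo = si)
  prof <- peak_repeat_profile(peaks, rpt, "class")
  expect_equal(prof$fraction[prof$category == "LINE"], 0.5)
  expect_equal(prof$fraction[prof$category == "SINE"], 0.5)
  expect_equal(prof$fraction[prof$category == "LTR"], 0)

  one <- peaks[1]
  prof1 <- peak_repeat_profile(one, rpt, "family")
  expect_equal(prof1$fraction[prof1$category == "L1"], 1)
  expect_equal(prof1$fraction[prof1$category == "Alu"], 1)
  expect_error(peak_repeat_profile(GenomicRanges::GRanges(seqinfo = si), rpt),
               "empty")
})

test_that("planted repeat targeting is recovered within binomial error", {
  set.seed(71)
  si <- fixture_genome(c(chr1 = 2e6))
  copies <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1000, 1.9e6, length.out = 60), width = 1000),
    seqinfo = si)
  copies$repeat_name <- "L1synth"; copies$repeat_class <- "LINE"
  copies$repeat_family <- "L1"
  n <- 1000
  on_copy <- runif(n) < 0.95
  start <- ifelse(on_copy,
                  GenomicRanges::start(copies)[sample(60, n, TRUE)] +
                    sample(0:900, n, TRUE),
                  sample(1:(2e6 - 200), n, TRUE))
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(start, start + 99),
                                  seqinfo = si)
  prof <- peak_repeat_profile(peaks, copies, "class")
  expect_lt(abs(prof$fraction[prof$category == "LINE"] - 0.95), 0.03)
})

test_that("LAD colocalization bookkeeping conserves the peak count", {
  si <- fixture_genome(c(chr1 = 100000))
  lads <- lad_map(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10000), seqinfo = si),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 15000), seqinfo = si))
  inside_c <- GenomicRanges::GRanges("chr1", IRanges::IRanges(500, 600),
                                     seqinfo = si)
  expect_equal(lad_colocalization(inside_c, lads),
               c(cLAD = 1, fLAD = 0, nonLAD = 0))
  straddle <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9500, 10500),
                                     seqinfo = si)
  expect_equal(lad_colocalization(straddle, lads),
               c(cLAD = 1, fLAD = 1, nonLAD = 0))

  set.seed(73)
  peaks <- random_intervals(si, 300, wmin = 50, wmax = 200)
  fr <- lad_colocalization(peaks, lads)
  in_any <- mean(count_overlaps(peaks, c(lads$clad, lads$flad)) > 0)
  expect_equal(unname(fr["nonLAD"] + in_any), 1)
})

test_that("random peaks fall in LADs at about the LAD genome share", {
  spec <- small_spec(lad_coverage = 0.5)
  si <- genome_index(spec$chrom_lengths)
  lads <- simulate_lads(si, spec)
  set.seed(75)
  peaks <- random_intervals(si, 1000, wmin = 1, wmax = 10)
  fr <- lad_colocalization(peaks, lads)
  expect_lt(abs((1 - fr[["nonLAD"]]) - 0.5), 0.05)
})

test_that("genome repartition reports per-set and union-complement shares", {
  si <- fixture_genome(c(chr1 = 1000))
  a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 400), seqinfo = si)
  b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 500), seqinfo = si)
  rep <- genome_repartition(list(A = a, B = b), si)
  expect_equal(rep[["A"]], 0.4)
  expect_equal(rep[["B"]], 0.3)
  expect_equal(rep[["non_A_B"]], 0.5)  # union [1,500]
  expect_equal(unname(genome_repartition(list(), si)), 1)
})

test_that("genomic context profile is non-exclusive with an exact complement", {
  si <- fixture_genome(c(chr1 = 10000))
  ctx <- list(
    gene_bodies = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2000),
                                         seqinfo = si),
    enhancers = GenomicRanges::GRanges("chr1", IRanges::IRanges(3000, 3500),
                                       seqinfo = si),
    cpg_islands = GenomicRanges::GRanges("chr1", IRanges::IRanges(1900, 1950),
                                         seqinfo = si))
  in_gene <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 200),
                                    seqinfo = si)
  expect_equal(genomic_context_profile(in_gene, ctx),
               c(gene_body = 1, enhancer = 0, cpg_island = 0, none_of_these = 0))
  both <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1890, 1960),
                                 seqinfo = si)
  p <- genomic_context_profile(both, ctx)
  expect_equal(p[["gene_body"]], 1)
  expect_equal(p[["cpg_island"]], 1)
  nowhere <- GenomicRanges::GRanges("chr1", IRanges::IRanges(8000, 8100),
                                    seqinfo = si)
  expect_equal(genomic_context_profile(nowhere, ctx)[["none_of_these"]], 1)
})

test_that("peak-set comparison captures many-to-one asymmetry and symmetry", {
  si <- fixture_genome(c(chr1 = 10000))
  a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000), seqinfo = si)
  b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(11, 501), c(20, 510)),
                              seqinfo = si)
  expect_equal(compare_peaksets(a, b),
               c(specific_a = 0L, shared_a = 1L, specific_b = 0L, shared_b = 2L))
  # swapping arguments swaps the fields exactly
  expect_equal(unname(compare_peaksets(b, a)),
               unname(compare_peaksets(a, b)[c(3, 4, 1, 2)]))

  far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, 5100),
                                seqinfo = si)
  expect_equal(compare_peaksets(a, far),
               c(specific_a = 1L, shared_a = 0L, specific_b = 1L, shared_b = 0L))
  expect_equal(unname(compare_peaksets(b, b)),
               c(0L, 2L, 0L, 2L))
})

test_that("consensus scanning is local and counts planted motifs", {
  set.seed(77)
  cons <- l1_consensus()
  res <- consensus_g4_count(c(L1 = cons))
  expect_equal(res$L1$count, 3)

  expect_equal(consensus_g4_count(c(x = strrep("T", 500)))$x$count, 0)
  padded <- paste0(strrep("AT", 100), cons, strrep("TA", 100))
  expect_equal(consensus_g4_count(c(p = padded))$p$count, 3)
  expect_error(consensus_g4_count(c(x = "")), "empty")
})
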