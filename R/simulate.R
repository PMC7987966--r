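#' Simulation specification for the synthetic study
#'
#' Defines the conditions the synthetic data emulates: a small random genome
#' carrying planted L1-like repeat copies (a conserved, low-divergence subset
#' retains its embedded canonical G4 motifs; the rest are degraded by point
#' substitutions), ChIP-seq-like peaks preferentially centered on conserved
#' copies, a LAD map covering about half the genome (60/40 cLAD/fLAD), a
#' differential-expression table with a 51% baseline upregulated fraction
#' plus a planted downregulation bias in a flagged gene subset, and paired
#' intensity vectors of stated correlation.
#'
#' @param chrom_lengths Named chromosome lengths (default two 2-Mb
#'   chromosomes).
#' @param gc_content Genome GC fraction (default 0.41, human-like).
#' @param n_repeat_copies Planted repeat copies (default 120).
#' @param conserved_fraction Fraction of copies left unmutated (default 0.4).
#' @param divergence_rate Per-base substitution probability for degraded
#'   copies (default 0.2, in the range of old L1 subfamilies).
#' @param n_peaks Peaks to simulate (default 400).
#' @param p_peak_on_conserved Probability a peak targets a conserved copy
#'   (default 0.9).
#' @param peak_width Mean and sd of peak widths in bp (default 600, 150),
#'   truncated at 50 bp.
#' @param lad_coverage Target LAD union coverage (default 0.5).
#' @param n_genes Genes tiling the genome (default 5000).
#' @param frac_up Baseline upregulated probability (default 0.51).
#' @param n_flagged Genes carrying the planted bias (default 50).
#' @param planted_down_bias Downregulation probability for flagged genes
#'   (default 0.8).
#' @param seed Global seed; per-generator streams are derived from it by
#'   fixed offsets.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(chrom_lengths = c(chrS1 = 2e6, chrS2 = 2e6),
                     gc_content = 0.41,
                     n_repeat_copies = 120L,
                     conserved_fraction = 0.4,
                     divergence_rate = 0.2,
                     n_peaks = 400L,
                     p_peak_on_conserved = 0.9,
                     peak_width = c(mean = 600, sd = 150),
                     lad_coverage = 0.5,
                     n_genes = 5000L,
                     frac_up = 0.51,
                     n_flagged = 50L,
                     planted_down_bias = 0.8,
                     seed = 1L) {
  fr <- c(gc_content = gc_content, conserved_fraction = conserved_fraction,
          divergence_rate = divergence_rate,
          p_peak_on_conserved = p_peak_on_conserved,
          lad_coverage = lad_coverage, frac_up = frac_up,
          planted_down_bias = planted_down_bias)
  if (any(fr < 0 | fr > 1))
    stop("fractions must lie in [0, 1]: ",
         paste(names(fr)[fr < 0 | fr > 1], collapse = ", "))
  if (any(chrom_lengths < 1)) stop("chromosome lengths must be positive")
  if (lad_coverage >= 1) stop("lad_coverage must be < 1")
  structure(list(chrom_lengths = chrom_lengths, gc_content = gc_content,
                 n_repeat_copies = as.integer(n_repeat_copies),
                 conserved_fraction = conserved_fraction,
                 divergence_rate = divergence_rate,
                 n_peaks = as.integer(n_peaks),
                 p_peak_on_conserved = p_peak_on_conserved,
                 peak_width = peak_width, lad_coverage = lad_coverage,
                 n_genes = as.integer(n_genes), frac_up = frac_up,
                 n_flagged = as.integer(n_flagged),
                 planted_down_bias = planted_down_bias,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

# fixed per-generator seed offsets (single global seed fanned out)
.sim_offsets <- c(genome = 101L, repeats = 202L, peaks = 303L,
                  de = 404L, intensity = 505L)

.sim_seed <- function(spec, stream) {
  (spec$seed + .sim_offsets[[stream]]) %% .Machine$integer.max
}

#' Generate a random genome at a target GC content
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = `gc_content / 2`.
#'
#' @param spec A [sim_spec()].
#' @return List with `sequences` (`DNAStringSet`) and `genome` (`Seqinfo`).
#' @export
make_genome <- function(spec = sim_spec()) {
  gc <- spec$gc_content
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- withr::with_seed(.sim_seed(spec, "genome"), {
    vapply(spec$chrom_lengths, function(L)
      paste(sample(names(prob), L, replace = TRUE, prob = prob),
            collapse = ""), "")
  })
  list(sequences = Biostrings::DNAStringSet(seqs),
       genome = genome_index(spec$chrom_lengths))
}

#' Synthetic L1-like consensus sequence
#'
#' A deterministic ~1.2-kb repeat consensus with three canonical G4 motifs
#' embedded (5' UTR-like, body and 3' UTR-like positions), mimicking the
#' G4-bearing structure of transcriptionally competent L1 elements. It is a
#' synthetic stand-in, not a RepBase/Dfam consensus.
#'
#' @param length Total consensus length (default 1200).
#' @return Nucleotide string.
#' @export
l1_consensus <- function(length = 1200L) {
  motifs <- c("GGGAGGGTGGGAGGG",
              "GGGGTTGGGGATGGGGTTGGGG",
              "GGGAGGGAGGGAGGG")
  body <- withr::with_seed(424242L, paste(
    sample(c("A", "C", "T"), length, replace = TRUE,
           prob = c(0.4, 0.25, 0.35)), collapse = ""))
  # plant at fixed relative offsets; C-free background keeps the motif count
  # at exactly three (no reverse-strand G4 can arise from A/C/T filler with
  # G only inside the planted runs)
  pos <- as.integer(length * c(0.08, 0.45, 0.85))
  for (i in seq_along(motifs)) {
    substr(body, pos[i], pos[i] + nchar(motifs[i]) - 1L) <- motifs[i]
  }
  substr(body, 1L, length)
}

.mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  hit <- which(runif(n) < rate)
  if (length(hit) == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  chars[hit] <- vapply(chars[hit], function(b)
    sample(setdiff(bases, b), 1), "")
  paste(chars, collapse = "")
}

#' Plant repeat copies into a genome
#'
#' Copies of the consensus are placed uniformly without overlapping each
#' other (bounded retries). A `conserved_fraction` subset is inserted
#' verbatim (divergence 0); the rest are degraded by per-base substitution
#' at `divergence_rate`. The truth table re-scans every planted copy with
#' the given params and records how many planted motifs survive mutation.
#'
#' @param genome Output of [make_genome()] (list with `sequences`,
#'   `genome`).
#' @param consensus Repeat consensus carrying canonical G4 motifs (default
#'   [l1_consensus()]).
#' @param spec A [sim_spec()].
#' @param params Params used to re-scan planted copies for surviving motifs.
#' @return List with `sequences` (mutated genome), `repeats` (a `GRanges`
#'   with rmsk-style metadata plus `conserved`, `milli_div` and
#'   `n_motifs_retained`).
#' @export
plant_repeats <- function(genome, consensus = l1_consensus(),
                          spec = sim_spec(),
                          params = quadparser_preset("canonical")) {
  lens <- spec$chrom_lengths
  w <- nchar(consensus)
  if (any(lens < w)) stop("consensus longer than a chromosome")
  n <- spec$n_repeat_copies
  seqs <- as.character(genome$sequences)
  res <- withr::with_seed(.sim_seed(spec, "repeats"), {
    placed <- GenomicRanges::GRanges(seqinfo = genome$genome)
    chrom <- character(n); start <- integer(n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in 1:1000) {
        r <- .randomize_core(w, names(lens), as.numeric(lens))
        cand <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$start, r$end),
                                       seqinfo = genome$genome)
        if (length(placed) == 0 ||
            sum(GenomicRanges::countOverlaps(cand, placed)) == 0) {
          placed <- c(placed, cand)
          chrom[i] <- r$chrom; start[i] <- r$start
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place all repeat copies without overlap")
    }
    conserved <- rep(FALSE, n)
    conserved[sample(n, round(spec$conserved_fraction * n))] <- TRUE
    copies <- character(n)
    for (i in seq_len(n)) {
      copies[i] <- if (conserved[i]) consensus
                   else .mutate_seq(consensus, spec$divergence_rate)
      substr(seqs[[chrom[i]]], start[i], start[i] + w - 1L) <- copies[i]
    }
    list(chrom = chrom, start = start, conserved = conserved, copies = copies)
  })
  retained <- vapply(res$copies, function(s)
    nrow(find_g4_motifs(s, params, "both")), integer(1), USE.NAMES = FALSE)
  div_obs <- vapply(res$copies, function(s)
    mean(strsplit(s, "")[[1]] != strsplit(consensus, "")[[1]]), numeric(1),
    USE.NAMES = FALSE)
  rpt <- GenomicRanges::GRanges(res$chrom,
                                IRanges::IRanges(res$start, res$start + w - 1L),
                                seqinfo = genome$genome)
  rpt$repeat_name <- ifelse(res$conserved, "L1synth_cons", "L1synth_div")
  rpt$repeat_class <- "LINE"
  rpt$repeat_family <- "L1"
  rpt$milli_div <- round(div_obs * 1000)
  rpt$conserved <- res$conserved
  rpt$n_motifs_retained <- retained
  o <- order(as.integer(GenomicRanges::seqnames(rpt)), GenomicRanges::start(rpt))
  list(sequences = Biostrings::DNAStringSet(seqs), repeats = rpt[o])
}

#' Simulate ChIP-seq-like peaks over planted repeats
#'
#' With probability `p_peak_on_conserved` a peak is centered on a uniformly
#' chosen position inside a random conserved repeat copy; otherwise it is
#' placed uniformly on the genome. Widths are normal
#' (`spec$peak_width`), truncated below at 50 bp, and clamped to chromosome
#' bounds.
#'
#' @param repeats `GRanges` from [plant_repeats()] (needs the `conserved`
#'   column).
#' @param spec A [sim_spec()].
#' @return `GRanges` of peaks with `name` and truth `label`
#'   (`on_conserved` / `background`).
#' @export
simulate_peaks <- function(repeats, spec = sim_spec()) {
  si <- .check_genome(repeats)
  cons <- repeats[repeats$conserved]
  if (length(cons) == 0 && spec$p_peak_on_conserved > 0)
    stop("no conserved copies to target")
  lens <- GenomeInfoDb::seqlengths(si)
  n <- spec$n_peaks
  withr::with_seed(.sim_seed(spec, "peaks"), {
    widths <- pmax(50L, as.integer(round(
      rnorm(n, spec$peak_width[["mean"]], spec$peak_width[["sd"]]))))
    targeted <- runif(n) < spec$p_peak_on_conserved
    chrom <- character(n); center <- integer(n)
    if (any(targeted)) {
      idx <- sample(length(cons), sum(targeted), replace = TRUE)
      chrom[targeted] <- as.character(GenomicRanges::seqnames(cons))[idx]
      center[targeted] <- as.integer(GenomicRanges::start(cons)[idx] +
        floor(runif(sum(targeted)) * GenomicRanges::width(cons)[idx]))
    }
    if (any(!targeted)) {
      r <- .randomize_core(rep(1, sum(!targeted)), names(lens),
                           as.numeric(lens))
      chrom[!targeted] <- r$chrom
      center[!targeted] <- r$start
    }
    start <- pmax(1L, center - widths %/% 2L)
    end <- pmin(as.integer(lens[chrom]), start + widths - 1L)
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                                 seqinfo = si)
    gr$name <- sprintf("peak_%04d", seq_len(n))
    gr$label <- ifelse(targeted, "on_conserved", "background")
    gr[order(as.integer(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr))]
  })
}

#' Simulate a LAD map of target coverage
#'
#' Deterministic alternating-block construction: each 250-kb period carries
#' one LAD block sized so the union coverage lands within 2% of
#' `lad_coverage`; blocks are assigned cyclically 3:2 to cLAD and fLAD
#' (60/40), which keeps the two maps disjoint.
#'
#' @param genome `Seqinfo` (or output of [make_genome()]).
#' @param spec A [sim_spec()].
#' @return A [lad_map()].
#' @export
simulate_lads <- function(genome, spec = sim_spec()) {
  si <- if (is(genome, "Seqinfo")) genome else genome$genome
  period <- 250000L
  lad_blocks <- GenomicRanges::GRanges(seqinfo = si)
  if (spec$lad_coverage > 0) {
    for (chr in GenomeInfoDb::seqnames(si)) {
      L <- GenomeInfoDb::seqlengths(si)[[chr]]
      starts <- seq(1L, L, by = period)
      block <- as.integer(round(pmin(period, L - starts + 1L) * spec$lad_coverage))
      keep <- block >= 1L
      lad_blocks <- c(lad_blocks, GenomicRanges::GRanges(
        chr, IRanges::IRanges(starts[keep], starts[keep] + block[keep] - 1L),
        seqinfo = si))
    }
  }
  n <- length(lad_blocks)
  if (n == 0)
    return(lad_map(GenomicRanges::GRanges(seqinfo = si),
                   GenomicRanges::GRanges(seqinfo = si)))
  # 60/40 split: take blocks largest-first, assigning each to whichever side
  # keeps the running cLAD share closest to 0.6 (robust to uneven blocks)
  w <- GenomicRanges::width(lad_blocks)
  is_c <- logical(n)
  c_bp <- 0; tot <- 0
  for (i in order(w, decreasing = TRUE)) {
    is_c[i] <- abs((c_bp + w[i]) / (tot + w[i]) - 0.6) <=
               abs(c_bp / (tot + w[i]) - 0.6)
    if (is_c[i]) c_bp <- c_bp + w[i]
    tot <- tot + w[i]
  }
  lad_map(lad_blocks[is_c], lad_blocks[!is_c])
}

#' Simulate gene intervals and a differential-expression table
#'
#' Genes tile the genome without overlap. Unflagged genes are upregulated
#' with probability `frac_up`; flagged genes with probability
#' `1 - planted_down_bias`. Fold-change magnitudes are lognormal.
#'
#' @param spec A [sim_spec()].
#' @param genome `Seqinfo` (or output of [make_genome()]).
#' @param flagged_genes Optional character vector of gene ids to flag;
#'   default draws `spec$n_flagged` genes at random.
#' @return List with `de` (data frame `gene_id`, `log2fc`, `pvalue`,
#'   `padj`), `genes` (`GRanges` with `name`) and `flagged`.
#' @export
simulate_de_table <- function(spec = sim_spec(), genome = NULL,
                              flagged_genes = NULL) {
  si <- if (is.null(genome)) genome_index(spec$chrom_lengths)
        else if (is(genome, "Seqinfo")) genome else genome$genome
  lens <- GenomeInfoDb::seqlengths(si)
  total <- sum(as.numeric(lens))
  slot <- floor(total / spec$n_genes)
  if (slot < 2) stop("too many genes for the genome size")
  gene_w <- max(1L, as.integer(slot * 0.75))
  ids <- sprintf("gene_%05d", seq_len(spec$n_genes))
  # deterministic tiling across chromosomes in index order
  bnd <- cumsum(as.numeric(lens))
  pos0 <- (seq_len(spec$n_genes) - 1) * slot
  ci <- findInterval(pos0, c(0, bnd), rightmost.closed = FALSE)
  start <- as.integer(pos0 - c(0, bnd)[ci] + 1)
  end <- pmin(as.integer(start + gene_w - 1L), lens[ci])
  genes <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(si)[ci],
                                  IRanges::IRanges(start, end), seqinfo = si)
  genes$name <- ids
  if (!is.null(flagged_genes) && !all(flagged_genes %in% ids))
    stop("flagged_genes outside the gene universe")
  withr::with_seed(.sim_seed(spec, "de"), {
    if (is.null(flagged_genes))
      flagged_genes <- sample(ids, spec$n_flagged)
    p_up <- ifelse(ids %in% flagged_genes, 1 - spec$planted_down_bias,
                   spec$frac_up)
    up <- runif(spec$n_genes) < p_up
    mag <- rlnorm(spec$n_genes, meanlog = 0, sdlog = 0.6)
    pvalue <- runif(spec$n_genes)^3
    de <- data.frame(gene_id = ids, log2fc = ifelse(up, mag, -mag),
                     pvalue = pvalue, padj = stats::p.adjust(pvalue, "BH"))
    list(de = de, genes = genes, flagged = flagged_genes)
  })
}

#' Simulate a paired intensity profile with a given correlation
#'
#' Bivariate normal pairs with correlation `rho`, shifted and scaled to
#' nonnegative arbitrary intensity units.
#'
#' @param rho Target correlation, `|rho| <= 1`.
#' @param n Number of paired positions.
#' @param seed Integer seed.
#' @return List with intensity vectors `a` and `b`.
#' @export
simulate_paired_intensities <- function(rho, n, seed = 1L) {
  if (abs(rho) > 1) stop("|rho| must be <= 1")
  withr::with_seed(as.integer(seed), {
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    list(a = pmax(0, 100 + 20 * z1), b = pmax(0, 100 + 20 * z2))
  })
}

#' Run the full synthetic-study generator
#'
#' Convenience wrapper producing every input the pipeline consumes, with
#' planted truths, and optionally writing them to standard files
#' (FASTA, BED, minimal rmsk TSV, DE TSV, JSON truth sidecar).
#'
#' @param spec A [sim_spec()].
#' @param dir Optional output directory.
#' @return List with `sequences`, `genome`, `repeats`, `peaks_a`, `peaks_b`,
#'   `lads`, `genes`, `de`, `flagged`, `spec` (and `files` when written).
#' @export
simulate_study <- function(spec = sim_spec(), dir = NULL) {
  g <- make_genome(spec)
  pr <- plant_repeats(g, l1_consensus(), spec)
  peaks_a <- simulate_peaks(pr$repeats, spec)
  spec_b <- spec; spec_b$seed <- spec$seed + 7L
  peaks_b <- simulate_peaks(pr$repeats, spec_b)
  lads <- simulate_lads(g$genome, spec)
  det <- simulate_de_table(spec, g$genome)
  out <- list(sequences = pr$sequences, genome = g$genome,
              repeats = pr$repeats, peaks_a = peaks_a, peaks_b = peaks_b,
              lads = lads, genes = det$genes, de = det$de,
              flagged = det$flagged, spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    f <- list(genome = file.path(dir, "genome.fa"),
              peaks_a = file.path(dir, "peaks_a.bed"),
              peaks_b = file.path(dir, "peaks_b.bed"),
              rmsk = file.path(dir, "repeats.rmsk.tsv"),
              clad = file.path(dir, "clad.bed"),
              flad = file.path(dir, "flad.bed"),
              genes = file.path(dir, "genes.bed"),
              de = file.path(dir, "de_table.tsv"),
              truth = file.path(dir, "truth.json"))
    Biostrings::writeXStringSet(out$sequences, f$genome)
    write_bed(peaks_a, f$peaks_a)
    write_bed(peaks_b, f$peaks_b)
    write_rmsk(out$repeats, f$rmsk)
    write_bed(lads$clad, f$clad)
    write_bed(lads$flad, f$flad)
    write_bed(det$genes, f$genes)
    write.table(det$de, f$de, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(
      seed = spec$seed,
      conserved_copies = sum(out$repeats$conserved),
      peaks_on_conserved_a = sum(peaks_a$label == "on_conserved"),
      peaks_on_conserved_b = sum(peaks_b$label == "on_conserved"),
      flagged_genes = det$flagged), f$truth, auto_unbox = TRUE, digits = NA)
    out$files <- f
  }
  out
}
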