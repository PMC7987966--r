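#' Quadparser scan parameters
#'
#' Parameter set for the regex-style G4 motif scan: a run of at least
#' `g_run_min` guanines, followed `n_runs - 1` times (or more, greedily) by a
#' loop of `loop_min`..`loop_max` bases and another G-run. The canonical
#' preset (4 runs of >= 3 G, loops 1-12 nt) is the most stringent canonical
#' G4 definition; the strictest shipped preset uses 5-G runs with 1-7 nt
#' loops, i.e. the pattern `([gG]{5,}\\w{1,7}){3,}[gG]{5,}`.
#'
#' @param g_run_min Minimum guanines per run (>= 2).
#' @param loop_min,loop_max Loop length bounds in bp (`loop_min >= 0`,
#'   `loop_min <= loop_max`).
#' @param n_runs Number of G-runs required (>= 4).
#' @return An object of class `quadparser_params`.
#' @export
#' @examples
#' quadparser_params(3, 1, 12, 4)  # canonical
quadparser_params <- function(g_run_min = 3L, loop_min = 1L, loop_max = 12L,
                              n_runs = 4L) {
  g_run_min <- as.integer(g_run_min); loop_min <- as.integer(loop_min)
  loop_max <- as.integer(loop_max); n_runs <- as.integer(n_runs)
  if (is.na(g_run_min) || g_run_min < 2) stop("g_run_min must be >= 2")
  if (is.na(n_runs) || n_runs < 4) stop("n_runs must be >= 4")
  if (is.na(loop_min) || loop_min < 0) stop("loop_min must be >= 0")
  if (is.na(loop_max) || loop_max < loop_min) stop("loop_max must be >= loop_min")
  structure(list(g_run_min = g_run_min, loop_min = loop_min,
                 loop_max = loop_max, n_runs = n_runs),
            class = "quadparser_params")
}

#' Named quadparser presets
#'
#' Four shipped parameter sets: `canonical` and `preset1` (3-G runs, loops
#' 1-12), `preset2` (3-G runs, loops 1-7) and `preset3` (5-G runs, loops
#' 1-7). Presets 1-3 approximate published stringency tiers and are labeled
#' approximate; all use 4 required runs.
#'
#' @param name One of `"canonical"`, `"preset1"`, `"preset2"`, `"preset3"`.
#' @return A `quadparser_params` object.
#' @export
quadparser_preset <- function(name = c("canonical", "preset1", "preset2", "preset3")) {
  switch(match.arg(name),
         canonical = quadparser_params(3, 1, 12, 4),
         preset1   = quadparser_params(3, 1, 12, 4),
         preset2   = quadparser_params(3, 1, 7, 4),
         preset3   = quadparser_params(5, 1, 7, 4))
}

#' @export
print.quadparser_params <- function(x, ...) {
  cat(sprintf("quadparser params: %d runs of >=%d G, loops %d-%d nt\n",
              x$n_runs, x$g_run_min, x$loop_min, x$loop_max))
  invisible(x)
}

.qp_pattern <- function(params) {
  sprintf("(?:[gG]{%d,}\\w{%d,%d}){%d,}[gG]{%d,}",
          params$g_run_min, params$loop_min, params$loop_max,
          params$n_runs - 1L, params$g_run_min)
}

# Maximal G-run coordinates of a sequence, via raw bytes (fast on Mb strings).
.g_runs <- function(seq) {
  y <- charToRaw(seq)
  isG <- y == as.raw(71L) | y == as.raw(103L)  # 'G' | 'g'
  r <- rle(isG)
  ends <- cumsum(r$lengths)
  list(start = (ends - r$lengths + 1L)[r$values], end = ends[r$values])
}

# Leftmost greedy non-overlapping matches of the quadparser pattern on one
# strand. A valid match can never contain a non-G stretch longer than
# loop_max, so the scan is confined to clusters of G-runs separated by gaps
# <= loop_max; the regex runs per cluster, which is equivalent to the global
# scan but much faster on chromosome-scale strings.
.qp_scan <- function(seq, params) {
  runs <- .g_runs(seq)
  if (length(runs$start) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  rl <- runs$end - runs$start + 1L
  brk <- c(TRUE, runs$start[-1] - runs$end[-length(runs$end)] - 1L > params$loop_max)
  cl <- cumsum(brk)
  cs <- runs$start[brk]
  ce <- runs$end[c(brk[-1], TRUE)]
  need <- params$n_runs * params$g_run_min
  tot <- as.integer(rowsum(as.numeric(rl), cl))
  mx <- vapply(split(rl, cl), max, integer(1), USE.NAMES = FALSE)
  keep <- which(tot >= need & mx >= params$g_run_min)
  pat <- .qp_pattern(params)
  starts <- integer(0); lens <- integer(0)
  for (i in keep) {
    m <- gregexpr(pat, substr(seq, cs[i], ce[i]), perl = TRUE)[[1]]
    if (m[1] != -1L) {
      starts <- c(starts, as.integer(m) + cs[i] - 1L)
      lens <- c(lens, attr(m, "match.length"))
    }
  }
  data.frame(start = starts, end = starts + lens - 1L)
}

# Maximal G-runs of length >= g_run_min inside a motif-strand substring,
# relative to the substring start.
.motif_runs <- function(seq, g_run_min) {
  r <- .g_runs(seq)
  keep <- (r$end - r$start + 1L) >= g_run_min
  IRanges::IRanges(r$start[keep], r$end[keep])
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Find G4 motifs in a nucleotide sequence
#'
#' Scans the forward strand with leftmost greedy non-overlapping matching of
#' the quadparser pattern; the minus strand is scanned on the reverse
#' complement and results are mapped back to forward coordinates. Matching is
#' case-insensitive.
#'
#' @param sequence Non-empty nucleotide string.
#' @param params A [quadparser_params()] object.
#' @param strands `"both"` (default), `"plus"` or `"minus"`.
#' @return Data frame with one row per motif: `start`, `end` (1-based,
#'   inclusive, forward strand), `strand`, `width`, `sequence` (forward
#'   strand orientation) and `runs`, a list column of [IRanges::IRanges]
#'   giving maximal G-runs (length >= `g_run_min`) relative to the motif on
#'   its own strand. Sorted by start, `+` before `-` at ties.
#' @export
#' @examples
#' find_g4_motifs("GGGAGGGAGGGAGGG", quadparser_preset("canonical"))
find_g4_motifs <- function(sequence, params = quadparser_preset("canonical"),
                           strands = c("both", "plus", "minus")) {
  strands <- match.arg(strands)
  if (!is(params, "quadparser_params")) stop("params must be quadparser_params")
  if (length(sequence) != 1 || is.na(sequence) || nchar(sequence) == 0)
    stop("sequence must be a single non-empty string")
  n <- nchar(sequence)
  hits <- list()
  if (strands %in% c("both", "plus")) {
    h <- .qp_scan(sequence, params)
    if (nrow(h)) h$strand <- "+"
    hits$plus <- h
  }
  if (strands %in% c("both", "minus")) {
    h <- .qp_scan(.revcomp(sequence), params)
    if (nrow(h)) {
      h <- data.frame(start = n - h$end + 1L, end = n - h$start + 1L,
                      strand = "-")
    }
    hits$minus <- h
  }
  hits <- hits[vapply(hits, nrow, 0L) > 0]
  out <- if (length(hits)) do.call(rbind, hits) else NULL
  if (is.null(out) || nrow(out) == 0) {
    out <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), width = integer(0),
                      sequence = character(0))
    out$runs <- list()
    return(out)
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out$width <- out$end - out$start + 1L
  out$sequence <- substring(sequence, out$start, out$end)
  strand_seq <- ifelse(out$strand == "+", out$sequence,
                       vapply(out$sequence, .revcomp, "", USE.NAMES = FALSE))
  out$runs <- lapply(strand_seq, .motif_runs, g_run_min = params$g_run_min)
  out
}

#' Predict a genome-wide G4 motif track
#'
#' Runs [find_g4_motifs()] per chromosome and assembles the results into a
#' stranded `GRanges` track.
#'
#' @param sequences Named character vector or [Biostrings::DNAStringSet] of
#'   chromosome sequences.
#' @param params A [quadparser_params()] object.
#' @param strands Strands to scan (see [find_g4_motifs()]).
#' @return A `GRanges` sorted by position with a `Seqinfo` built from the
#'   sequence lengths.
#' @export
genome_g4_track <- function(sequences, params = quadparser_preset("canonical"),
                            strands = "both") {
  if (is(sequences, "DNAStringSet")) sequences <- as.character(sequences)
  if (is.null(names(sequences))) stop("sequences must be named by chromosome")
  si <- genome_index(stats::setNames(nchar(sequences), names(sequences)))
  per <- lapply(names(sequences), function(chr) {
    m <- find_g4_motifs(sequences[[chr]], params, strands)
    if (nrow(m) == 0) return(GenomicRanges::GRanges(seqinfo = si))
    GenomicRanges::GRanges(chr, IRanges::IRanges(m$start, m$end),
                           strand = m$strand, seqinfo = si)
  })
  out <- suppressWarnings(do.call(c, per))
  out[order(as.integer(GenomicRanges::seqnames(out)),
            GenomicRanges::start(out),
            as.integer(GenomicRanges::strand(out)))]
}

#' Fraction of peaks containing a predicted G4 motif
#'
#' Peaks are extended by `flank` bp on each side (clamped to chromosome
#' bounds) and overlapping motifs are counted; the fraction is the share of
#' peaks whose extended interval overlaps at least one motif.
#'
#' @param peaks Non-empty `GRanges` of peaks.
#' @param g4_track `GRanges` of predicted motifs on the same genome.
#' @param flank Extension in bp (default 50).
#' @return List with `fraction` and the per-peak integer `counts`.
#' @export
peaks_with_g4_fraction <- function(peaks, g4_track, flank = 50L) {
  if (length(peaks) == 0) stop("empty peak set: fraction undefined")
  counts <- count_overlaps(extend_clamped(peaks, flank), g4_track)
  list(fraction = mean(counts > 0), counts = counts)
}

#' Best QGRS G-score of a sequence
#'
#' Enumerates every four-run quadruplex-forming G-rich sequence candidate
#' (runs of at least `g_run_min` G, loops of 0..`loop_max` bases, which may
#' split longer G-runs) and scores each with
#' `score = 20 * (t - 2) + sum(loop_max - l_i) - (max(l) - min(l))`,
#' where `t` is the shortest of the four run lengths and `l_1..l_3` the loop
#' lengths: more tetrads, shorter loops and equal loops score higher. This
#' scoring function is defined by this package in the spirit of QGRS-style
#' scores; it is not the QGRS Mapper program.
#'
#' Intended for motif-scale sequences (tens to a few hundred bases);
#' enumeration cost grows quickly with G density.
#'
#' @param sequence Nucleotide string.
#' @param g_run_min Minimum G-run length (default 2).
#' @param loop_max Maximum loop length (default 12).
#' @return `NULL` when no candidate exists, else a list with `tetrads`,
#'   `loops` (length 3), `score`, `start`, `end` and `sequence` of the best
#'   candidate (ties: leftmost, then shortest).
#' @export
#' @examples
#' qgrs_best_score("GGGTGGGTGGGTGGG")$score  # 53
qgrs_best_score <- function(sequence, g_run_min = 2L, loop_max = 12L) {
  g_run_min <- as.integer(g_run_min); loop_max <- as.integer(loop_max)
  if (length(sequence) != 1 || is.na(sequence) || nchar(sequence) == 0)
    return(NULL)
  n <- nchar(sequence)
  y <- charToRaw(sequence)
  isG <- y == as.raw(71L) | y == as.raw(103L)
  # grun[i]: length of the G-run starting at i (0 when position i is not G)
  grun <- integer(n)
  run <- 0L
  for (i in n:1) {
    run <- if (isG[i]) run + 1L else 0L
    grun[i] <- run
  }
  cand_start <- which(grun >= g_run_min)
  if (length(cand_start) == 0) return(NULL)
  best <- NULL
  score_of <- function(t, loops)
    20L * (t - 2L) + sum(loop_max - loops) - (max(loops) - min(loops))
  consider <- function(p1, e4, t, loops) {
    s <- score_of(t, loops)
    if (is.null(best) || s > best$score ||
        (s == best$score && (p1 < best$start ||
                             (p1 == best$start && e4 < best$end)))) {
      best <<- list(tetrads = t, loops = loops, score = s,
                    start = p1, end = e4,
                    sequence = substring(sequence, p1, e4))
    }
  }
  for (p1 in cand_start) {
    for (r1 in g_run_min:grun[p1]) {
      if (p1 + r1 > n) break
      for (p2 in (p1 + r1):min(n, p1 + r1 + loop_max)) {
        if (grun[p2] < g_run_min) next
        l1 <- p2 - (p1 + r1)
        for (r2 in g_run_min:grun[p2]) {
          if (p2 + r2 > n) break
          for (p3 in (p2 + r2):min(n, p2 + r2 + loop_max)) {
            if (grun[p3] < g_run_min) next
            l2 <- p3 - (p2 + r2)
            for (r3 in g_run_min:grun[p3]) {
              if (p3 + r3 > n) break
              for (p4 in (p3 + r3):min(n, p3 + r3 + loop_max)) {
                if (grun[p4] < g_run_min) next
                l3 <- p4 - (p3 + r3)
                # score-optimal final run: longest useful, then shortest span
                r4 <- min(grun[p4], min(r1, r2, r3))
                consider(p1, p4 + r4 - 1L,
                         min(r1, r2, r3, r4), c(l1, l2, l3))
              }
            }
          }
        }
      }
    }
  }
  best
}
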