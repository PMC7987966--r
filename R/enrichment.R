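# Internal numeric representation of an interval set for the permutation
# loop: chromosome index, start, end (1-based closed), plus sorted feature
# endpoints per chromosome for O(log m) overlap counting.

.feature_index <- function(features) {
  by_chr <- split(data.frame(s = GenomicRanges::start(features),
                             e = GenomicRanges::end(features)),
                  as.character(GenomicRanges::seqnames(features)))
  lapply(by_chr, function(d) list(s = sort(d$s), e = sort(d$e)))
}

# Number of features overlapping each query interval by >= 1 bp:
# #(feature start <= qe) - #(feature end < qs), per chromosome.
.fast_counts <- function(chrom, qs, qe, fidx) {
  out <- integer(length(qs))
  for (chr in unique(chrom)) {
    i <- which(chrom == chr)
    fx <- fidx[[chr]]
    if (is.null(fx)) next
    out[i] <- findInterval(qe[i], fx$s) - findInterval(qs[i] - 1L, fx$e)
  }
  out
}

.stat_from_counts <- function(counts, statistic) {
  switch(statistic,
         fraction_overlapping = mean(counts > 0),
         total_overlap_count = sum(counts))
}

# Randomized probe placement matched in widths: chromosome with probability
# proportional to (length - width + 1), start uniform over valid positions.
# The setup (per-interval valid-position counts) is computed once; each draw
# consumes exactly one runif(n), so the RNG stream is independent of whether
# the setup is reused across draws.
.randomize_setup <- function(widths, chrom_names, chrom_lens) {
  valid <- pmax(outer(chrom_lens, widths, function(L, w) L - w + 1), 0)
  tot <- colSums(valid)
  if (any(tot == 0))
    stop("interval wider than every chromosome (width ",
         max(widths[tot == 0]), ")")
  list(widths = widths, chrom_names = chrom_names,
       C = length(chrom_lens), n = length(widths),
       cs = apply(valid, 2, cumsum), tot = tot)
}

.randomize_draw <- function(setup) {
  u <- floor(runif(setup$n) * setup$tot) + 1
  if (setup$C == 1L) {
    ci <- rep(1L, setup$n)
    start <- u
  } else {
    below <- colSums(setup$cs < rep(u, each = setup$C))
    ci <- below + 1L
    prev <- ifelse(below == 0, 0,
                   setup$cs[cbind(pmax(below, 1L), seq_len(setup$n))])
    start <- u - prev
  }
  list(chrom = setup$chrom_names[ci], start = as.integer(start),
       end = as.integer(start + setup$widths - 1))
}

.randomize_core <- function(widths, chrom_names, chrom_lens) {
  .randomize_draw(.randomize_setup(widths, chrom_names, chrom_lens))
}

#' Randomly reposition intervals across the genome
#'
#' Each interval keeps its width and is placed uniformly among all valid
#' positions genome-wide (chromosome drawn with probability proportional to
#' the number of valid start positions it offers). Outputs may overlap each
#' other; assembly gaps are not masked.
#'
#' @param set A `GRanges` with chromosome lengths in its `seqinfo`.
#' @param genome Optional `Seqinfo` to draw on (defaults to the set's).
#' @param seed Optional integer seed; when given the draw is reproducible
#'   and the caller's RNG state is untouched.
#' @return A `GRanges` of matched widths, strand `*`.
#' @export
randomize_regions <- function(set, genome = NULL, seed = NULL) {
  si <- .check_genome(set, genome)
  draw <- function() {
    r <- .randomize_core(GenomicRanges::width(set),
                         GenomeInfoDb::seqnames(si),
                         as.numeric(GenomeInfoDb::seqlengths(si)))
    GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$start, r$end),
                           seqinfo = si)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

.null_matrix <- function(peaks, fidx_list, statistic, n_perm, flank, genome) {
  widths <- GenomicRanges::width(peaks)
  chrom_names <- GenomeInfoDb::seqnames(genome)
  chrom_lens <- as.numeric(GenomeInfoDb::seqlengths(genome))
  setup <- .randomize_setup(widths, chrom_names, chrom_lens)
  out <- matrix(NA_real_, nrow = n_perm, ncol = length(fidx_list))
  for (p in seq_len(n_perm)) {
    r <- .randomize_draw(setup)
    qs <- pmax(1L, r$start - as.integer(flank))
    qe <- pmin(as.integer(chrom_lens[match(r$chrom, chrom_names)]),
               r$end + as.integer(flank))
    for (j in seq_along(fidx_list)) {
      out[p, j] <- .stat_from_counts(
        .fast_counts(r$chrom, qs, qe, fidx_list[[j]]), statistic)
    }
  }
  out
}

.perm_row <- function(observed, null, n_perm, seed, statistic, alternative) {
  null_mean <- mean(null)
  null_sd <- sd(null)
  degenerate <- is.na(null_sd) || null_sd == 0
  z <- if (degenerate) 0 else (observed - null_mean) / null_sd
  extreme <- if (alternative == "enrichment") sum(null >= observed)
             else sum(null <= observed)
  list(observed = observed, null_mean = null_mean,
       null_sd = if (degenerate) 0 else null_sd, z = z,
       p_emp = (1 + extreme) / (n_perm + 1), n_perm = n_perm,
       seed = if (is.null(seed)) NA_integer_ else seed,
       statistic_name = statistic, degenerate = degenerate,
       alternative = alternative)
}

#' Permutation test for peak-feature colocalization
#'
#' The observed statistic (fraction of peaks overlapping at least one
#' feature, or total overlap count) is compared with a null distribution
#' built from `n_perm` randomly repositioned, width-matched probe sets (see
#' [randomize_regions()]); any `flank` is applied to the observed peaks and
#' to every null draw alike. The empirical p-value uses the add-one
#' correction `(1 + #extreme) / (n_perm + 1)`, so it is never exactly zero.
#'
#' @param peaks Non-empty `GRanges` of peaks.
#' @param feature Non-empty `GRanges` of features, same genome.
#' @param statistic `"fraction_overlapping"` (default) or
#'   `"total_overlap_count"`.
#' @param n_perm Number of permutations (default 1000).
#' @param flank Extension applied to peaks before counting (default 0).
#' @param seed Optional integer seed for the null draws.
#' @param alternative `"enrichment"` (observed >= null, default) or
#'   `"depletion"`.
#' @return A `g4_permtest` list: `observed`, `null_mean`, `null_sd`, `z`
#'   (reported as 0 with `degenerate = TRUE` when the null has zero spread),
#'   `p_emp`, `n_perm`, `seed`, `statistic_name`.
#' @export
permutation_enrichment <- function(peaks, feature,
                                   statistic = c("fraction_overlapping",
                                                 "total_overlap_count"),
                                   n_perm = 1000L, flank = 0L, seed = NULL,
                                   alternative = c("enrichment", "depletion")) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  if (length(peaks) == 0) stop("empty peak set")
  if (length(feature) == 0) stop("empty feature set")
  if (n_perm < 1) stop("n_perm must be >= 1")
  si <- .check_genome(peaks)
  observed <- .stat_from_counts(
    count_overlaps(extend_clamped(peaks, flank), feature), statistic)
  fidx <- .feature_index(feature)
  null <- if (is.null(seed)) {
    .null_matrix(peaks, list(fidx), statistic, n_perm, flank, si)
  } else {
    withr::with_seed(seed, .null_matrix(peaks, list(fidx), statistic,
                                        n_perm, flank, si))
  }
  structure(.perm_row(observed, null[, 1], n_perm, seed, statistic,
                      alternative),
            class = "g4_permtest")
}

#' @export
print.g4_permtest <- function(x, ...) {
  cat(sprintf("permutation test (%s, %d perms): observed %.4g, null %.4g +/- %.4g\n",
              x$statistic_name, x$n_perm, x$observed, x$null_mean, x$null_sd))
  cat(sprintf("  z = %.2f%s, empirical p (%s) = %.4g\n", x$z,
              if (x$degenerate) " [degenerate null]" else "",
              x$alternative, x$p_emp))
  invisible(x)
}

#' Permutation enrichment against several feature sets at once
#'
#' All feature sets are scored against the same stream of randomized probe
#' sets (one draw per permutation index), so rows are directly comparable.
#'
#' @param peaks Non-empty `GRanges`.
#' @param features Named list of `GRanges` feature sets.
#' @param statistic,n_perm,flank,seed,alternative As in
#'   [permutation_enrichment()].
#' @return Data frame with one row per feature: `feature`, `observed`,
#'   `null_mean`, `null_sd`, `z`, `p_emp`, `n_perm`, `seed`, `degenerate`.
#' @export
multi_feature_enrichment <- function(peaks, features,
                                     statistic = c("fraction_overlapping",
                                                   "total_overlap_count"),
                                     n_perm = 1000L, flank = 0L, seed = NULL,
                                     alternative = c("enrichment", "depletion")) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  if (!is.list(features)) stop("features must be a named list of GRanges")
  if (length(features) == 0) {
    return(data.frame(feature = character(0), observed = numeric(0),
                      null_mean = numeric(0), null_sd = numeric(0),
                      z = numeric(0), p_emp = numeric(0),
                      n_perm = integer(0), seed = integer(0),
                      degenerate = logical(0)))
  }
  if (is.null(names(features)) || any(names(features) == ""))
    stop("features must be named")
  if (length(peaks) == 0) stop("empty peak set")
  si <- .check_genome(peaks)
  ext <- extend_clamped(peaks, flank)
  observed <- vapply(features, function(f)
    .stat_from_counts(count_overlaps(ext, f), statistic), numeric(1))
  fidx_list <- lapply(features, .feature_index)
  null <- if (is.null(seed)) {
    .null_matrix(peaks, fidx_list, statistic, n_perm, flank, si)
  } else {
    withr::with_seed(seed, .null_matrix(peaks, fidx_list, statistic,
                                        n_perm, flank, si))
  }
  rows <- lapply(seq_along(features), function(j)
    .perm_row(observed[j], null[, j], n_perm, seed, statistic, alternative))
  data.frame(feature = names(features),
             observed = vapply(rows, `[[`, 0, "observed"),
             null_mean = vapply(rows, `[[`, 0, "null_mean"),
             null_sd = vapply(rows, `[[`, 0, "null_sd"),
             z = vapply(rows, `[[`, 0, "z"),
             p_emp = vapply(rows, `[[`, 0, "p_emp"),
             n_perm = n_perm,
             seed = if (is.null(seed)) NA_integer_ else seed,
             degenerate = vapply(rows, `[[`, TRUE, "degenerate"),
             row.names = NULL)
}
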