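#' Pearson correlation of a paired intensity line profile
#'
#' Colocalization statistic for two markers measured along the same line
#' profile (or the same set of cells): the standard Pearson correlation of
#' the paired intensity vectors.
#'
#' @param a,b Equal-length numeric vectors (length >= 3, finite, each with
#'   nonzero variance).
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_profile <- function(a, b) {
  if (length(a) != length(b)) stop("intensity vectors must have equal length")
  if (length(a) < 3) stop("need at least 3 paired intensities")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("intensities must be finite")
  if (sd(a) == 0 || sd(b) == 0)
    stop("zero-variance intensity vector: correlation undefined")
  cor(a, b, method = "pearson")
}

#' K-means grouping of per-cell intensities
#'
#' Lloyd's algorithm with `k` initial centers sampled (by seed) from the
#' data rows themselves, run for up to `n_iter` update rounds with early
#' exit on convergence. Reports per-cluster Pearson correlation between two
#' markers, the statistic used to read scatter plots of co-labeled cells.
#'
#' @param table Data frame or matrix of per-cell intensities; non-numeric
#'   columns (for instance a cell id) are dropped for clustering.
#' @param k Number of groups, 2 or 3.
#' @param n_iter Maximum Lloyd update rounds (default 20).
#' @param seed Integer seed making initialization deterministic.
#' @param n_start Number of seeded random-point restarts (default 1); with
#'   more than one, the run with the lowest total within-cluster sum of
#'   squares wins. Single random-point starts can land in split-blob local
#'   optima, so raise this when group recovery matters.
#' @param markers Length-2 character vector naming the columns used for the
#'   per-cluster correlation (default: the first two numeric columns).
#' @return List with `labels` (integer cluster per row), `centers`,
#'   `cluster_r` (per-cluster Pearson between the two markers; `NA` for
#'   clusters with under 3 cells or zero variance) and `tot_withinss`.
#' @export
kmeans_cells <- function(table, k = c(2L, 3L), n_iter = 20L, seed = 1L,
                         n_start = 1L, markers = NULL) {
  k <- as.integer(k[1])
  if (!k %in% c(2L, 3L)) stop("k must be 2 or 3")
  x <- as.data.frame(table)
  num <- vapply(x, is.numeric, TRUE)
  mat <- as.matrix(x[, num, drop = FALSE])
  if (nrow(mat) < k) stop("fewer rows than clusters")
  if (ncol(mat) < 2) stop("need at least two numeric marker columns")
  if (is.null(markers)) markers <- colnames(mat)[1:2]
  fit <- withr::with_seed(seed, {
    best <- NULL
    for (s in seq_len(max(1L, n_start))) {
      centers <- mat[sample(nrow(mat), k), , drop = FALSE]
      f <- tryCatch(
        suppressWarnings(kmeans(mat, centers = centers, iter.max = n_iter,
                                algorithm = "Lloyd")),
        error = function(e) NULL)  # empty-cluster starts are discarded
      if (!is.null(f) && (is.null(best) || f$tot.withinss < best$tot.withinss))
        best <- f
    }
    if (is.null(best)) stop("all k-means starts produced an empty cluster")
    best
  })
  cluster_r <- vapply(seq_len(k), function(ci) {
    rows <- fit$cluster == ci
    a <- mat[rows, markers[1]]
    b <- mat[rows, markers[2]]
    if (sum(rows) < 3 || sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }, numeric(1))
  list(labels = unname(fit$cluster), centers = fit$centers,
       cluster_r = cluster_r, tot_withinss = fit$tot.withinss)
}

#' Box-plot summary statistics of an intensity vector
#'
#' Five-number summary in the convention used for the package's intensity
#' box plots: whiskers at the minimum and maximum, box at the 25th and 75th
#' percentiles (linear interpolation), and the center line at the **mean**
#' (not the median).
#'
#' @param values Non-empty numeric vector.
#' @return Named numeric vector `c(min, q25, mean, q75, max)`.
#' @export
box_stats <- function(values) {
  if (length(values) == 0) stop("empty input")
  if (any(!is.finite(values))) stop("values must be finite")
  q <- unname(quantile(values, c(0.25, 0.75), type = 7))
  c(min = min(values), q25 = q[1], mean = mean(values), q75 = q[2],
    max = max(values))
}

#' Read paired intensity line profiles
#'
#' @param path Tab-separated file with header columns `label`, `position`,
#'   `channel_a`, `channel_b`.
#' @return Named list (per label) of lists with vectors `a` and `b`, ordered
#'   by position.
#' @export
read_intensity_profiles <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  miss <- setdiff(c("label", "position", "channel_a", "channel_b"), names(tab))
  if (length(miss))
    stop("profile table missing columns: ", paste(miss, collapse = ", "))
  lapply(split(tab, tab$label), function(d) {
    d <- d[order(d$position), ]
    list(a = d$channel_a, b = d$channel_b)
  })
}

#' Read a per-cell intensity table
#'
#' @param path Tab-separated file with header column `cell_id` followed by
#'   one numeric column per marker.
#' @return Data frame.
#' @export
read_cell_table <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(tab)) stop("cell table missing column cell_id")
  tab
}
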