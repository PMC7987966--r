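#' Read a differential-expression table
#'
#' @param path Tab-separated file with header columns `gene_id`, `log2fc`,
#'   `pvalue`, `padj` (extra columns kept).
#' @return Data frame of per-gene expression contrast records.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "pvalue", "padj")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("DE table missing columns: ", paste(miss, collapse = ", "))
  tab$log2fc <- as.numeric(tab$log2fc)
  tab$pvalue <- as.numeric(tab$pvalue)
  tab$padj <- as.numeric(tab$padj)
  if (any(tab$padj < 0 | tab$padj > 1, na.rm = TRUE))
    stop("padj outside [0, 1]")
  tab
}

.splicing_categories <- c("minor_isoform_loss", "gap_junction", "cryptic_fusion")

#' Read a splicing-event call table
#'
#' @param path Tab-separated file with header columns `gene_id` and
#'   `category`; categories must come from the fixed vocabulary
#'   `minor_isoform_loss` (loss of a minor isoform), `gap_junction`
#'   (formation of a large splicing gap) and `cryptic_fusion` (read-through
#'   fusion transcript into a neighboring locus).
#' @return Data frame of splicing calls.
#' @export
read_splicing_calls <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  miss <- setdiff(c("gene_id", "category"), names(tab))
  if (length(miss))
    stop("splicing table missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(tab$category), .splicing_categories)
  if (length(bad))
    stop("unknown splicing categories: ", paste(bad, collapse = ", "),
         " (expected ", paste(.splicing_categories, collapse = ", "), ")")
  tab
}

#' Assign peaks to the genes they overlap
#'
#' A peak is assigned to every named gene body it overlaps by at least 1 bp
#' (unextended); intergenic peaks get an empty gene set.
#'
#' @param peaks `GRanges`.
#' @param genes `GRanges` with a non-missing `name` metadata column.
#' @return List (one element per peak) of character vectors of gene names.
#' @export
assign_peaks_to_genes <- function(peaks, genes) {
  if (is.null(genes$name) || anyNA(genes$name))
    stop("gene intervals must be named (a 'name' metadata column)")
  hits <- GenomicRanges::findOverlaps(peaks, genes, ignore.strand = TRUE)
  out <- rep(list(character(0)), length(peaks))
  if (length(hits)) {
    by_peak <- split(genes$name[S4Vectors::subjectHits(hits)],
                     S4Vectors::queryHits(hits))
    out[as.integer(names(by_peak))] <- lapply(by_peak, unique)
  }
  out
}

.de_direction <- function(de) {
  ifelse(de$log2fc > 0, "up", ifelse(de$log2fc < 0, "down", NA))
}

#' Fraction of direction-classified genes that are upregulated
#'
#' Genes with `log2fc == 0` are excluded from numerator and denominator.
#'
#' @param de DE table (see [read_de_table()]).
#' @return `up / (up + down)`.
#' @export
#' @examples
#' # the worked example: 2006 up and 1924 down gives the 51% baseline
#' de <- data.frame(gene_id = as.character(1:3930),
#'                  log2fc = c(rep(1, 2006), rep(-1, 1924)),
#'                  pvalue = 0.01, padj = 0.05)
#' upregulated_fraction(de)
upregulated_fraction <- function(de) {
  dir <- .de_direction(de)
  n_up <- sum(dir == "up", na.rm = TRUE)
  n_down <- sum(dir == "down", na.rm = TRUE)
  if (n_up + n_down == 0) stop("no direction-classified genes")
  n_up / (n_up + n_down)
}

#' Exact binomial test for expression-direction bias in a gene set
#'
#' Given a baseline probability that a gene is upregulated (for instance the
#' genome-wide upregulated fraction of the contrast), tests whether a gene
#' subset is biased toward down- or upregulation. Both one-sided exact
#' binomial tails are reported:
#' `p_enriched_down = P(X <= k_up)` and `p_enriched_up = P(X >= k_up)` for
#' `X ~ Binomial(n, baseline_up)`.
#'
#' @param genes Character vector of gene ids.
#' @param de DE table; genes absent from it (or with `log2fc == 0`) are
#'   ignored.
#' @param baseline_up Baseline upregulated probability in (0, 1).
#' @return List with `n`, `k_up`, `p_enriched_down`, `p_enriched_up`.
#' @export
direction_binomial_test <- function(genes, de, baseline_up = 0.51) {
  if (baseline_up <= 0 || baseline_up >= 1)
    stop("baseline_up must be in (0, 1)")
  dir <- .de_direction(de)
  keep <- de$gene_id %in% unique(genes) & !is.na(dir)
  n <- sum(keep)
  if (n == 0) stop("no genes from the set have a direction in the DE table")
  k_up <- sum(dir[keep] == "up")
  list(n = n, k_up = k_up,
       p_enriched_down = pbinom(k_up, n, baseline_up),
       p_enriched_up = pbinom(k_up - 1L, n, baseline_up, lower.tail = FALSE))
}

#' Summarize splicing calls and expression direction per peak class
#'
#' For each peak class (for instance lost-in-disease / common /
#' gained-in-disease gene sets) reports the gene count, how many genes carry
#' any splicing-event call, per-category call counts, and the
#' direction-binomial test restricted to genes with a splicing call.
#'
#' @param classes Named list of character vectors of gene ids.
#' @param calls Splicing call table (see [read_splicing_calls()]).
#' @param de DE table.
#' @param baseline_up Baseline for [direction_binomial_test()].
#' @return Data frame with one row per class: `class`, `n_genes`,
#'   `n_spliced`, one count column per splicing category, `n_tested`,
#'   `k_up`, `p_enriched_down`, `p_enriched_up`, `test_skipped`.
#' @export
summarize_peak_splicing <- function(classes, calls, de, baseline_up = 0.51) {
  rows <- lapply(names(classes), function(cl) {
    genes <- unique(classes[[cl]])
    cc <- calls[calls$gene_id %in% genes, , drop = FALSE]
    spliced <- unique(cc$gene_id)
    per_cat <- vapply(.splicing_categories, function(cat)
      length(unique(cc$gene_id[cc$category == cat])), integer(1))
    test <- NULL
    if (length(spliced)) {
      dir <- .de_direction(de)
      if (any(de$gene_id %in% spliced & !is.na(dir)))
        test <- direction_binomial_test(spliced, de, baseline_up)
    }
    data.frame(class = cl, n_genes = length(genes),
               n_spliced = length(spliced),
               as.list(per_cat),
               n_tested = if (is.null(test)) 0L else test$n,
               k_up = if (is.null(test)) NA_integer_ else test$k_up,
               p_enriched_down = if (is.null(test)) NA_real_ else test$p_enriched_down,
               p_enriched_up = if (is.null(test)) NA_real_ else test$p_enriched_up,
               test_skipped = is.null(test))
  })
  do.call(rbind, rows)
}
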