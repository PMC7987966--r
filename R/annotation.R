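#' Read a RepeatMasker annotation table
#'
#' Accepts the UCSC `rmsk` table dialect (header naming at least `genoName`,
#' `genoStart`, `genoEnd`, `repName`, `repClass`, `repFamily`; `genoStart`
#' 0-based half-open; `milliDiv` and `strand` carried through when present)
#' or a minimal headerless 6-column dialect
#' `chrom  start  end  name  class  family` with 0-based half-open
#' coordinates.
#'
#' @param path Tab-separated repeat annotation file.
#' @param genome Optional `Seqinfo`; when given, records are validated
#'   against it and the result is bound to it.
#' @return A `GRanges` with metadata columns `repeat_name`, `repeat_class`,
#'   `repeat_family` and, when present in the input, `milli_div`.
#' @export
read_rmsk <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  has_header <- grepl("genoName", first, fixed = TRUE)
  if (has_header) {
    tab <- read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, comment.char = "")
    names(tab) <- sub("^X\\.", "", names(tab))  # '#bin' style headers
    need <- c("genoName", "genoStart", "genoEnd", "repName", "repClass",
              "repFamily")
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop("rmsk file missing required columns: ", paste(miss, collapse = ", "))
    d <- data.frame(chrom = tab$genoName,
                    start0 = suppressWarnings(as.integer(tab$genoStart)),
                    end = suppressWarnings(as.integer(tab$genoEnd)),
                    name = tab$repName, class = tab$repClass,
                    family = tab$repFamily,
                    strand = if ("strand" %in% names(tab)) tab$strand else "*",
                    milli_div = if ("milliDiv" %in% names(tab))
                      suppressWarnings(as.numeric(tab$milliDiv)) else NA_real_,
                    stringsAsFactors = FALSE)
    offset <- 1L  # header line
  } else {
    tab <- read.delim(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE)
    if (ncol(tab) < 6)
      stop("minimal rmsk dialect needs 6 columns (chrom/start/end/name/class/family)")
    d <- data.frame(chrom = as.character(tab[[1]]),
                    start0 = suppressWarnings(as.integer(tab[[2]])),
                    end = suppressWarnings(as.integer(tab[[3]])),
                    name = as.character(tab[[4]]), class = as.character(tab[[5]]),
                    family = as.character(tab[[6]]), strand = "*",
                    milli_div = if (ncol(tab) >= 7)
                      suppressWarnings(as.numeric(tab[[7]])) else NA_real_,
                    stringsAsFactors = FALSE)
    offset <- 0L
  }
  bad <- which(is.na(d$start0) | is.na(d$end))
  if (length(bad)) stop("line ", bad[1] + offset, ": non-integer coordinates")
  bad <- which(d$start0 >= d$end)
  if (length(bad))
    stop("line ", bad[1] + offset, ": start >= end (", d$start0[bad[1]], " >= ",
         d$end[bad[1]], ")")
  if (any(!nzchar(d$name)) || any(!nzchar(d$class)) || any(!nzchar(d$family)))
    stop("empty repeat name/class/family")
  d$strand[!d$strand %in% c("+", "-")] <- "*"
  if (!is.null(genome)) {
    bad <- which(!d$chrom %in% GenomeInfoDb::seqnames(genome))
    if (length(bad))
      stop("line ", bad[1] + offset, ": chromosome '", d$chrom[bad[1]],
           "' absent from genome")
  }
  gr <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start0 + 1L, d$end),
                               strand = d$strand,
                               seqinfo = genome)
  gr$repeat_name <- d$name
  gr$repeat_class <- d$class
  gr$repeat_family <- d$family
  if (!all(is.na(d$milli_div))) gr$milli_div <- d$milli_div
  gr
}

#' Write repeat records in the minimal rmsk dialect
#'
#' @param repeats `GRanges` from [read_rmsk()] or [plant_repeats()].
#' @param path Output file (tab-separated, 0-based half-open, no header).
#' @export
write_rmsk <- function(repeats, path) {
  md <- if (is.null(repeats$milli_div)) rep(0, length(repeats)) else repeats$milli_div
  writeLines(paste(as.character(GenomicRanges::seqnames(repeats)),
                   GenomicRanges::start(repeats) - 1L,
                   GenomicRanges::end(repeats),
                   repeats$repeat_name, repeats$repeat_class,
                   repeats$repeat_family, md, sep = "\t"), path)
  invisible(path)
}

.membership_fraction <- function(peaks, feature_gr, categories) {
  hits <- GenomicRanges::findOverlaps(peaks, feature_gr, ignore.strand = TRUE)
  out <- vapply(split(S4Vectors::queryHits(hits),
                      categories[S4Vectors::subjectHits(hits)]),
                function(q) length(unique(q)) / length(peaks), numeric(1))
  all_cat <- sort(unique(categories))
  stats::setNames(ifelse(is.na(out[all_cat]), 0, out[all_cat]), all_cat)
}

#' Fraction of peaks containing each repeat category
#'
#' Membership is non-exclusive: one peak can contain a combination of repeat
#' elements and counts in every category it overlaps, so fractions may sum
#' above 1.
#'
#' @param peaks Non-empty `GRanges`.
#' @param repeats `GRanges` from [read_rmsk()].
#' @param level `"class"` (LINE/SINE/...), `"family"` (L1/Alu/...) or
#'   `"name"` (finest).
#' @return Data frame with `category` and `fraction` (peaks overlapping at
#'   least one element of the category, over all peaks).
#' @export
peak_repeat_profile <- function(peaks, repeats,
                                level = c("class", "family", "name")) {
  level <- match.arg(level)
  if (length(peaks) == 0) stop("empty peak set")
  categories <- switch(level, class = repeats$repeat_class,
                       family = repeats$repeat_family,
                       name = repeats$repeat_name)
  frac <- .membership_fraction(peaks, repeats, categories)
  data.frame(category = names(frac), fraction = unname(frac),
             row.names = NULL)
}

#' Bundle constitutive and facultative LAD interval sets
#'
#' @param clad,flad `GRanges` of constitutive and facultative
#'   lamina-associated domains on the same genome.
#' @return A `lad_map` list.
#' @export
lad_map <- function(clad, flad) {
  if (!.same_genome(clad, flad))
    stop("cLAD and fLAD sets are bound to different genomes")
  structure(list(clad = clad, flad = flad), class = "lad_map")
}

#' Peak colocalization with lamina-associated domains
#'
#' cLAD and fLAD membership are non-exclusive (a peak straddling both counts
#' in both); `nonLAD` is the fraction overlapping neither, so
#' `nonLAD + (cLAD union fLAD membership) = 1` exactly.
#'
#' @param peaks Non-empty `GRanges`.
#' @param lads A [lad_map()].
#' @return Named numeric vector `c(cLAD, fLAD, nonLAD)`.
#' @export
lad_colocalization <- function(peaks, lads) {
  if (length(peaks) == 0) stop("empty peak set")
  in_c <- count_overlaps(peaks, lads$clad) > 0
  in_f <- count_overlaps(peaks, lads$flad) > 0
  c(cLAD = mean(in_c), fLAD = mean(in_f), nonLAD = mean(!in_c & !in_f))
}

#' Genome coverage repartition of named feature sets
#'
#' Per-name coverage fractions are computed on merged intervals and may
#' double-count overlaps between sets; the complement (`non_`) slice is the
#' uncovered fraction of their union, so it never double-counts.
#'
#' @param features Named list of `GRanges`.
#' @param genome `Seqinfo` denominator.
#' @return Named numeric vector of per-set fractions plus `non_<...>`
#'   complement of the union.
#' @export
genome_repartition <- function(features, genome) {
  per <- vapply(features, coverage_fraction, numeric(1), genome = genome)
  union_frac <- if (length(features) == 0) 0 else
    coverage_fraction(GenomicRanges::reduce(
      do.call(c, lapply(unname(features), GenomicRanges::granges)),
      ignore.strand = TRUE), genome)
  comp <- stats::setNames(1 - union_frac,
                          paste0("non_", paste(names(features), collapse = "_")))
  if (length(features) == 0) comp <- c(non_feature = 1)
  c(per, comp)
}

#' Genomic-context profile of a peak set
#'
#' Non-exclusive membership fractions against gene bodies, enhancers and CpG
#' islands, plus the fraction of peaks touching none of the three.
#'
#' @param peaks Non-empty `GRanges`.
#' @param context Named list with elements `gene_bodies`, `enhancers`,
#'   `cpg_islands` (each a `GRanges`).
#' @return Named numeric vector
#'   `c(gene_body, enhancer, cpg_island, none_of_these)`.
#' @export
genomic_context_profile <- function(peaks, context) {
  if (length(peaks) == 0) stop("empty peak set")
  need <- c("gene_bodies", "enhancers", "cpg_islands")
  miss <- setdiff(need, names(context))
  if (length(miss)) stop("context missing: ", paste(miss, collapse = ", "))
  in_g <- count_overlaps(peaks, context$gene_bodies) > 0
  in_e <- count_overlaps(peaks, context$enhancers) > 0
  in_c <- count_overlaps(peaks, context$cpg_islands) > 0
  c(gene_body = mean(in_g), enhancer = mean(in_e), cpg_island = mean(in_c),
    none_of_these = mean(!in_g & !in_e & !in_c))
}

#' Compare two peak sets by mutual overlap
#'
#' Shared counts are computed per set: `shared_a` is the number of intervals
#' of `a` overlapping at least one interval of `b`, and symmetrically for
#' `b`. The two shared counts can differ when several intervals of one set
#' fall inside a single large interval of the other (many-to-one overlap),
#' which is why condition-specific and shared peak counts need not add up
#' symmetrically.
#'
#' @param a,b `GRanges` on the same genome.
#' @return Named integer vector
#'   `c(specific_a, shared_a, specific_b, shared_b)`.
#' @export
compare_peaksets <- function(a, b) {
  if (!.same_genome(a, b)) stop("peak sets are bound to different genomes")
  shared_a <- sum(count_overlaps(a, b) > 0)
  shared_b <- sum(count_overlaps(b, a) > 0)
  c(specific_a = length(a) - shared_a, shared_a = shared_a,
    specific_b = length(b) - shared_b, shared_b = shared_b)
}

#' Scan repeat consensus sequences for G4 motifs
#'
#' Runs [find_g4_motifs()] (both strands) on each consensus sequence,
#' reporting counts and consensus-relative motif coordinates. Used to ask
#' whether a repeat family's consensus carries canonical G4 motifs.
#'
#' @param consensus Named character vector (or `DNAStringSet`) of consensus
#'   sequences.
#' @param params A [quadparser_params()] object.
#' @return Named list per consensus with `count` and `motifs` (the
#'   [find_g4_motifs()] data frame).
#' @export
consensus_g4_count <- function(consensus,
                               params = quadparser_preset("canonical")) {
  if (is(consensus, "DNAStringSet")) consensus <- as.character(consensus)
  if (any(!nzchar(consensus))) stop("empty consensus sequence")
  out <- lapply(consensus, function(s) {
    m <- find_g4_motifs(s, params, "both")
    list(count = nrow(m), motifs = m)
  })
  stats::setNames(out, names(consensus))
}
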