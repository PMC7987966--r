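#' @importFrom methods is
#' @importFrom stats cor dbinom kmeans pbinom quantile rbinom rlnorm rnorm runif sd
#' @importFrom utils read.delim write.table
NULL

#' Build a genome index from chromosome lengths
#'
#' The genome index is the coordinate universe for all interval sets in the
#' package: an ordered chromosome name -> length map, represented as a
#' [GenomeInfoDb::Seqinfo] object.
#'
#' @param lengths Named integer vector of chromosome lengths in bp (all >= 1,
#'   names unique).
#' @return A `Seqinfo` object.
#' @export
#' @examples
#' genome_index(c(chr1 = 1000, chr2 = 500))
genome_index <- function(lengths) {
  if (is.null(names(lengths)) || anyNA(names(lengths)) || any(names(lengths) == ""))
    stop("chromosome lengths must be named")
  if (anyDuplicated(names(lengths)))
    stop("duplicate chromosome names: ",
         paste(unique(names(lengths)[duplicated(names(lengths))]), collapse = ", "))
  if (any(!is.finite(lengths)) || any(lengths < 1))
    stop("chromosome lengths must be positive integers")
  GenomeInfoDb::Seqinfo(seqnames = names(lengths), seqlengths = as.integer(lengths))
}

#' Read a two-column chromosome-sizes file
#'
#' @param path Tab-separated file with columns chromosome name, length.
#' @return A `Seqinfo` object.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("chrom-sizes file needs two columns: ", path)
  len <- suppressWarnings(as.integer(tab[[2]]))
  if (anyNA(len)) stop("non-integer length in chrom-sizes file: ", path)
  genome_index(stats::setNames(len, as.character(tab[[1]])))
}

#' Read a genome FASTA file
#'
#' Records are uppercased; IUPAC ambiguity characters beyond A/C/G/T/N are
#' kept but flagged with a warning.
#'
#' @param path FASTA file.
#' @return A list with elements `sequences` (a [Biostrings::DNAStringSet])
#'   and `genome` (the matching `Seqinfo`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("no FASTA records in ", path)
  # FASTA headers may carry descriptions after the record name
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA record name: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (any(Biostrings::width(seqs) == 0))
    stop("empty FASTA record: ",
         paste(names(seqs)[Biostrings::width(seqs) == 0], collapse = ", "))
  freq <- Biostrings::alphabetFrequency(seqs, collapse = TRUE)
  odd <- freq[setdiff(names(freq), c("A", "C", "G", "T", "N"))]
  if (sum(odd) > 0)
    warning("non-ACGTN characters in ", path, ": ",
            paste0(names(odd)[odd > 0], "=", odd[odd > 0], collapse = ", "))
  list(sequences = seqs,
       genome = genome_index(stats::setNames(Biostrings::width(seqs), names(seqs))))
}

.check_genome <- function(gr, genome = NULL) {
  si <- if (is.null(genome)) GenomeInfoDb::seqinfo(gr) else genome
  if (any(is.na(GenomeInfoDb::seqlengths(si))))
    stop("genome index with missing chromosome lengths")
  si
}

.same_genome <- function(a, b) {
  la <- GenomeInfoDb::seqlengths(a)
  lb <- GenomeInfoDb::seqlengths(b)
  identical(la[order(names(la))], lb[order(names(lb))])
}

#' Read a BED file of genomic intervals
#'
#' BED coordinates (0-based, half-open) are converted to the 1-based closed
#' convention of `GRanges` on input; [write_bed()] converts back, so BED
#' round-trips are exact. Columns beyond the sixth are ignored.
#'
#' @param path BED3/BED6 file (tab-separated).
#' @param genome `Seqinfo` the intervals must fit.
#' @return A `GRanges` bound to `genome`, in file order, with `name` and
#'   `score` metadata columns when present.
#' @export
read_bed <- function(path, genome) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(GenomicRanges::GRanges(seqinfo = genome))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 3))
    stop("line ", which(n < 3)[1], ": fewer than 3 BED columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end))
  if (length(bad)) stop("line ", bad[1], ": non-integer coordinates")
  bad <- which(start0 >= end)
  if (length(bad))
    stop("line ", bad[1], ": start >= end (", start0[bad[1]], " >= ", end[bad[1]], ")")
  bad <- which(start0 < 0)
  if (length(bad)) stop("line ", bad[1], ": negative start")
  known <- GenomeInfoDb::seqnames(genome)
  bad <- which(!chrom %in% known)
  if (length(bad))
    stop("line ", bad[1], ": chromosome '", chrom[bad[1]], "' absent from genome")
  lens <- GenomeInfoDb::seqlengths(genome)[chrom]
  bad <- which(end > lens)
  if (length(bad))
    stop("line ", bad[1], ": end ", end[bad[1]], " beyond chromosome length ",
         lens[bad[1]])
  name <- ifelse(n >= 4, vapply(fields, function(f) f[min(4L, length(f))], ""), NA)
  score <- ifelse(n >= 5, vapply(fields, function(f) f[min(5L, length(f))], ""), NA)
  strand <- ifelse(n >= 6, vapply(fields, function(f) f[min(6L, length(f))], ""), "*")
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start0 + 1L, end),
                               strand = strand, seqinfo = genome)
  if (any(n >= 4)) gr$name <- ifelse(is.na(name) | name == ".", NA_character_, name)
  if (any(n >= 5)) gr$score <- suppressWarnings(as.numeric(score))
  gr
}

#' Write intervals to a BED file
#'
#' Writes BED6 when name/score/strand information is present, BED3 otherwise.
#'
#' @param set A `GRanges`.
#' @param path Output file.
#' @export
write_bed <- function(set, path) {
  start0 <- GenomicRanges::start(set) - 1L
  end <- GenomicRanges::end(set)
  chrom <- as.character(GenomicRanges::seqnames(set))
  strand <- as.character(GenomicRanges::strand(set))
  has6 <- !is.null(set$name) || !is.null(set$score) || any(strand != "*")
  if (has6) {
    name <- if (is.null(set$name)) rep(".", length(set)) else ifelse(is.na(set$name), ".", set$name)
    score <- if (is.null(set$score)) rep(0, length(set)) else ifelse(is.na(set$score), 0, set$score)
    strand[strand == "*"] <- "."
    out <- paste(chrom, start0, end, name, score, strand, sep = "\t")
  } else {
    out <- paste(chrom, start0, end, sep = "\t")
  }
  writeLines(out, path)
  invisible(path)
}

#' Extend intervals by a flank, clamped to chromosome bounds
#'
#' Each interval grows by `flank` bp on each side, clipped at position 1 and
#' at the chromosome length. Used with the default 50 bp flank when
#' annotating ChIP-seq peaks for G4 motif content.
#'
#' @param set A `GRanges` with chromosome lengths in its `seqinfo`.
#' @param flank Non-negative flank in bp.
#' @return A `GRanges` of the same length.
#' @export
extend_clamped <- function(set, flank) {
  if (length(flank) != 1 || is.na(flank) || flank < 0)
    stop("flank must be a single non-negative number")
  si <- .check_genome(set)
  lens <- GenomeInfoDb::seqlengths(si)[as.character(GenomicRanges::seqnames(set))]
  out <- set
  IRanges::ranges(out) <- IRanges::IRanges(
    pmax(1L, GenomicRanges::start(set) - as.integer(flank)),
    pmin(lens, GenomicRanges::end(set) + as.integer(flank))
  )
  out
}

#' Count overlapping subject intervals per query interval
#'
#' Strand-agnostic overlap counting: the count for each query interval is the
#' number of subject intervals sharing at least `min_overlap` bases with it.
#' Abutting intervals (zero shared bases) never count.
#'
#' @param query,subject `GRanges` on the same genome.
#' @param min_overlap Minimum shared bases (default 1, the common
#'   "colocalized" definition).
#' @return Integer vector, one count per query interval.
#' @export
count_overlaps <- function(query, subject, min_overlap = 1L) {
  if (!.same_genome(query, subject))
    stop("query and subject are bound to different genomes")
  unname(GenomicRanges::countOverlaps(query, subject,
                                      minoverlap = as.integer(min_overlap),
                                      ignore.strand = TRUE))
}

#' Fraction of the genome covered by an interval set
#'
#' Intervals are merged (de-overlapped) before counting, so the result is
#' invariant under splitting intervals into abutting pieces.
#'
#' @param set A `GRanges`.
#' @param genome `Seqinfo` giving the denominator; defaults to the set's own.
#' @return Covered fraction in \[0, 1\].
#' @export
coverage_fraction <- function(set, genome = NULL) {
  si <- .check_genome(set, genome)
  total <- sum(as.numeric(GenomeInfoDb::seqlengths(si)))
  if (length(set) == 0) return(0)
  covered <- sum(as.numeric(GenomicRanges::width(
    GenomicRanges::reduce(set, ignore.strand = TRUE))))
  covered / total
}
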