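#' Build an analysis configuration
#'
#' Paths may be left `NULL`; stages whose inputs are missing are skipped
#' gracefully and marked as such in the report. Conditions are labeled
#' generically (`condition_a` / `condition_b`).
#'
#' @param genome Path to the genome FASTA.
#' @param peaks_a,peaks_b Paths to per-condition peak BED files.
#' @param rmsk Path to a repeat annotation table ([read_rmsk()] dialects).
#' @param clad,flad Paths to LAD BED files.
#' @param gene_bodies,enhancers,cpg_islands Paths to context BED files.
#' @param de_table Path to the differential-expression TSV.
#' @param splicing_calls Path to the splicing-call TSV.
#' @param preset Quadparser preset name (see [quadparser_preset()]).
#' @param flank Peak extension for G4 annotation in bp (default 50).
#' @param n_perm Permutations for enrichment tests (default 1000).
#' @param baseline_up Baseline upregulated fraction for direction tests;
#'   `NULL` (default) computes it from the DE table.
#' @param seed Integer seed recorded in every output.
#' @param out_dir Output directory; `NULL` keeps results in memory only.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(genome, peaks_a, peaks_b = NULL, rmsk = NULL,
                            clad = NULL, flad = NULL, gene_bodies = NULL,
                            enhancers = NULL, cpg_islands = NULL,
                            de_table = NULL, splicing_calls = NULL,
                            preset = "canonical", flank = 50L,
                            n_perm = 1000L, baseline_up = NULL, seed = 1L,
                            out_dir = NULL) {
  cfg <- list(genome = genome, peaks_a = peaks_a, peaks_b = peaks_b,
              rmsk = rmsk, clad = clad, flad = flad,
              gene_bodies = gene_bodies, enhancers = enhancers,
              cpg_islands = cpg_islands, de_table = de_table,
              splicing_calls = splicing_calls, preset = preset,
              flank = as.integer(flank), n_perm = as.integer(n_perm),
              baseline_up = baseline_up, seed = as.integer(seed),
              out_dir = out_dir)
  paths <- unlist(cfg[c("genome", "peaks_a", "peaks_b", "rmsk", "clad",
                        "flad", "gene_bodies", "enhancers", "cpg_islands",
                        "de_table", "splicing_calls")])
  missing <- paths[!vapply(paths, file.exists, TRUE)]
  if (length(missing))
    stop("configured files not found: ", paste(missing, collapse = ", "))
  structure(cfg, class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Flat key-value YAML with the fields of [analysis_config()]; relative
#' paths are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return An `analysis_config` list.
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  path_keys <- c("genome", "peaks_a", "peaks_b", "rmsk", "clad", "flad",
                 "gene_bodies", "enhancers", "cpg_islands", "de_table",
                 "splicing_calls", "out_dir")
  for (k in intersect(path_keys, names(raw))) {
    if (!is.null(raw[[k]]) && !grepl("^(/|[A-Za-z]:)", raw[[k]]))
      raw[[k]] <- file.path(base, raw[[k]])
  }
  do.call(analysis_config, raw)
}

.config_fingerprint <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(unclass(config)[order(names(config))], tmp)
  unname(tools::md5sum(tmp))
}

.stage <- function(name, expr) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full G4 landscape analysis
#'
#' Orchestrates predict -> annotate -> enrich -> compare -> link on the
#' configured inputs, logging one line per stage, and returns (optionally
#' writes) a machine-readable report. Deterministic for a fixed seed.
#'
#' @param config An [analysis_config()] or path to a YAML config.
#' @return A `g4_report` list with sections `g4_track`, `peak_g4`,
#'   `enrichment`, `profiles`, `comparison`, `expression` and `provenance`.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  report <- list(provenance = list(
    package = as.character(utils::packageVersion("g4scape")),
    seed = config$seed, preset = config$preset,
    config_md5 = .config_fingerprint(config)))

  fa <- .stage("read genome", read_fasta(config$genome))
  params <- quadparser_preset(config$preset)
  track <- .stage("predict G4 track",
                  genome_g4_track(fa$sequences, params, "both"))
  report$g4_track <- list(
    n_motifs = length(track),
    genome_coverage = coverage_fraction(track, fa$genome))

  peaks <- list(condition_a = .stage("read peaks_a",
                                     read_bed(config$peaks_a, fa$genome)))
  if (!is.null(config$peaks_b))
    peaks$condition_b <- .stage("read peaks_b",
                                read_bed(config$peaks_b, fa$genome))
  report$peak_g4 <- .stage("annotate peaks for G4", lapply(peaks, function(p)
    list(n_peaks = length(p),
         g4_fraction = peaks_with_g4_fraction(p, track, config$flank)$fraction)))

  repeats <- if (!is.null(config$rmsk))
    .stage("read repeats", read_rmsk(config$rmsk, fa$genome)) else NULL
  lads <- if (!is.null(config$clad) && !is.null(config$flad))
    .stage("read LADs", lad_map(read_bed(config$clad, fa$genome),
                                read_bed(config$flad, fa$genome))) else NULL
  context <- if (!is.null(config$gene_bodies))
    .stage("read context", list(
      gene_bodies = read_bed(config$gene_bodies, fa$genome),
      enhancers = if (is.null(config$enhancers))
        GenomicRanges::GRanges(seqinfo = fa$genome)
        else read_bed(config$enhancers, fa$genome),
      cpg_islands = if (is.null(config$cpg_islands))
        GenomicRanges::GRanges(seqinfo = fa$genome)
        else read_bed(config$cpg_islands, fa$genome))) else NULL

  features <- list(g4_motifs = track)
  if (!is.null(repeats)) {
    for (cl in unique(repeats$repeat_class))
      features[[paste0("repeat_", cl)]] <- repeats[repeats$repeat_class == cl]
  }
  if (!is.null(lads)) {
    features$cLAD <- lads$clad
    features$fLAD <- lads$flad
  }
  report$enrichment <- .stage("permutation enrichment", lapply(
    peaks, multi_feature_enrichment, features = features,
    statistic = "fraction_overlapping", n_perm = config$n_perm,
    flank = 0L, seed = config$seed))

  report$profiles <- .stage("annotation profiles", lapply(peaks, function(p) {
    out <- list()
    if (!is.null(repeats)) {
      out$repeat_class <- peak_repeat_profile(p, repeats, "class")
      out$repeat_family <- peak_repeat_profile(p, repeats, "family")
    }
    if (!is.null(lads)) {
      out$lad <- as.list(lad_colocalization(p, lads))
      out$lad_genome <- as.list(genome_repartition(
        list(cLAD = lads$clad, fLAD = lads$flad), fa$genome))
    }
    if (!is.null(context)) out$context <- as.list(genomic_context_profile(p, context))
    out
  }))

  classes <- NULL
  if (length(peaks) == 2) {
    cmp <- .stage("compare peak sets",
                  compare_peaksets(peaks$condition_a, peaks$condition_b))
    report$comparison <- as.list(cmp)
    if (!is.null(context)) {
      genes <- context$gene_bodies
      if (!is.null(genes$name)) {
        ga <- assign_peaks_to_genes(peaks$condition_a, genes)
        gb <- assign_peaks_to_genes(peaks$condition_b, genes)
        in_b <- count_overlaps(peaks$condition_a, peaks$condition_b) > 0
        in_a <- count_overlaps(peaks$condition_b, peaks$condition_a) > 0
        classes <- list(
          lost_in_b = unique(unlist(ga[!in_b])),
          common = unique(c(unlist(ga[in_b]), unlist(gb[in_a]))),
          gained_in_b = unique(unlist(gb[!in_a])))
        report$peak_classes <- lapply(classes, length)
      }
    }
  }

  if (!is.null(config$de_table)) {
    de <- .stage("read DE table", read_de_table(config$de_table))
    baseline <- if (is.null(config$baseline_up)) upregulated_fraction(de)
                else config$baseline_up
    expr <- list(upregulated_fraction = upregulated_fraction(de),
                 baseline_up = baseline)
    if (!is.null(classes)) {
      expr$direction <- lapply(classes, function(g) {
        if (length(g) == 0) return(list(skipped = TRUE))
        direction_binomial_test(g, de, baseline)
      })
      if (!is.null(config$splicing_calls)) {
        calls <- .stage("read splicing calls",
                        read_splicing_calls(config$splicing_calls))
        expr$splicing <- summarize_peak_splicing(classes, calls, de, baseline)
      }
    }
    report$expression <- expr
  } else {
    report$expression <- list(skipped = TRUE)
  }

  class(report) <- "g4_report"
  if (!is.null(config$out_dir)) .write_report(report, config$out_dir)
  report
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (cond in names(report$enrichment)) {
    write.table(report$enrichment[[cond]],
                file.path(out_dir, paste0("enrichment_", cond, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$expression$splicing))
    write.table(report$expression$splicing,
                file.path(out_dir, "splicing_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  invisible(out_dir)
}

#' @export
print.g4_report <- function(x, ...) {
  cat("G4 landscape analysis report\n")
  cat(sprintf("  G4 track: %d motifs, %.3f%% genome coverage\n",
              x$g4_track$n_motifs, 100 * x$g4_track$genome_coverage))
  for (cond in names(x$peak_g4))
    cat(sprintf("  %s: %d peaks, %.1f%% with a G4 motif\n", cond,
                x$peak_g4[[cond]]$n_peaks,
                100 * x$peak_g4[[cond]]$g4_fraction))
  if (!is.null(x$comparison))
    cat(sprintf("  comparison: %d a-specific / %d shared-a; %d b-specific / %d shared-b\n",
                x$comparison$specific_a, x$comparison$shared_a,
                x$comparison$specific_b, x$comparison$shared_b))
  invisible(x)
}
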