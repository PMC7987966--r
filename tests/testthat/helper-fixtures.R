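# Programmatic fixtures shared across tests.

fixture_genome <- function(lengths = c(chr1 = 10000, chr2 = 5000)) {
  g4scape::genome_index(lengths)
}

random_intervals <- function(genome, n, wmin = 10L, wmax = 500L) {
  lens <- GenomeInfoDb::seqlengths(genome)
  w <- sample(wmin:wmax, n, replace = TRUE)
  chr <- sample(names(lens), n, replace = TRUE, prob = as.numeric(lens))
  start <- vapply(seq_len(n), function(i)
    sample.int(lens[[chr[i]]] - w[i] + 1L, 1L), integer(1))
  GenomicRanges::GRanges(chr, IRanges::IRanges(start, start + w - 1L),
                         seqinfo = genome)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# small spec so whole-pipeline tests stay fast
small_spec <- function(...) {
  args <- utils::modifyList(
    list(chrom_lengths = c(chrA = 4e5, chrB = 3e5),
         n_repeat_copies = 40L, n_peaks = 120L, n_genes = 600L),
    list(...))
  do.call(g4scape::sim_spec, args)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
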