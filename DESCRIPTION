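Package: g4scape
Title: G-Quadruplex Landscape Annotation and Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts G-quadruplex (G4) motifs over genome sequences with a
    parameterized quadparser-style regular-expression scan, annotates ChIP-seq
    peak sets for G4, repeat-element, lamina-associated-domain and genomic
    context content, assesses colocalization with permutation nulls built from
    randomly repositioned probe sets, compares peak sets between conditions,
    and links intragenic peaks to expression direction (exact binomial tests
    against a stated baseline) and splicing-event categories. Includes
    quantification statistics for imaging colocalization (line-profile Pearson
    correlation, K-means grouping of per-cell intensities) and a synthetic-data
    generator that emulates a genome with planted repeat copies, peaks, LAD
    maps and differential-expression tables so the whole pipeline runs at desk
    scale with recoverable planted truths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
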