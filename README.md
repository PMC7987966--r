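# g4scape

Annotation and enrichment analysis of the genomic G-quadruplex (G4)
landscape.

G-quadruplexes are four-stranded DNA secondary structures formed by stacked
guanine tetrads. Where they can form is largely encoded in sequence: four
runs of at least *g* guanines separated by loops of bounded length,

```
(G{g,} N{lmin,lmax}) x 3   followed by   G{g,}
```

the canonical definition being four runs of ≥ 3 G with loops of 1–12 nt.
`g4scape` is for epigenomics analysts who have G4-directed (or
G4-associated) ChIP-seq peak sets and want to know what those peaks sit on:
predicted G4 motifs, repeat elements (LINE/L1, SINE/Alu), lamina-associated
domains (LADs), gene bodies / enhancers / CpG islands — and whether those
colocalizations beat a random-placement null, how two conditions' peak sets
relate, and whether peak-associated genes are biased toward up- or
downregulation.

The statistical core:

* **Quadparser-style motif scan** — greedy, non-overlapping, case-insensitive
  regex matching on both strands, with named stringency presets and an
  explicit QGRS-style G-score
  `20·(t−2) + Σ(loop_max − lᵢ) − (max l − min l)` rewarding more tetrads,
  shorter and equal loops.
* **Permutation enrichment** — observed overlap statistics against nulls
  from width-matched, uniformly repositioned probe sets;
  `z = (obs − μ₀)/σ₀` and the add-one empirical p
  `(1 + #{null ≥ obs})/(n_perm + 1)`.
* **Exact binomial direction test** — for a gene set with `k_up` of `n`
  genes upregulated against a baseline `b`, both one-sided tails
  `P(X ≤ k_up)` and `P(X ≥ k_up)`, `X ~ Bin(n, b)`.
* **Imaging quantifications** — line-profile Pearson colocalization, seeded
  K-means grouping of per-cell intensities, box summaries with a mean
  center line.
* **Synthetic-data generator** — a desk-scale genome with planted
  G4-bearing repeat copies, peaks, LAD maps and expression tables, so every
  stage is testable with recoverable truths.

## Worked example

Everything below runs in seconds on a laptop; no downloads needed.

```r
library(g4scape)

# simulate a desk-scale study (two 2-Mb chromosomes, planted L1-like copies)
st <- simulate_study(sim_spec(seed = 42))

# predict the canonical G4 track and annotate the peaks
track <- genome_g4_track(st$sequences, quadparser_preset("canonical"))
length(track)
#> [1] 203
peaks_with_g4_fraction(st$peaks_a, track, flank = 50)$fraction
#> [1] 0.8825

# permutation enrichment of peaks over conserved repeat copies
permutation_enrichment(st$peaks_a, st$repeats[st$repeats$conserved],
                       n_perm = 1000, seed = 42)
#> permutation test (fraction_overlapping, 1000 perms): observed 0.89, null 0.02123 +/- 0.0069
#>   z = 125.91, empirical p (enrichment) = 0.000999

# direction bias of the flagged gene subset against the 51% baseline
direction_binomial_test(st$flagged, st$de, baseline_up = 0.51)[c("n", "k_up", "p_enriched_down")]
#> $n
#> [1] 50
#> $k_up
#> [1] 12
#> $p_enriched_down
#> [1] 8.863029e-05

qgrs_best_score("GGGTGGGTGGGTGGG")$score
#> [1] 53
```

Reading the output: 203 canonical motifs are predicted on the 4-Mb
synthetic genome; 88% of peaks carry a motif within 50 bp (the generator
plants 90% of peaks on conserved, motif-bearing repeat copies); the
conserved-copy enrichment is maximally significant (p = 1/1001, the
smallest value 1000 permutations can produce) with an enormous z because
random probes rarely land on the ~3% of the genome the copies cover; and
the flagged gene subset (planted 80% down) shows only 12 of 50 genes up,
p ≈ 9×10⁻⁵ against the 51% baseline.

Real inputs come in through `read_fasta()`, `read_bed()`, `read_rmsk()`
(UCSC or minimal dialect), `read_de_table()` and `read_splicing_calls()`;
`run_analysis()` drives the whole pipeline from a YAML config, and
`inst/scripts/g4scape.R` exposes `predict` / `enrich` / `simulate` / `run`
subcommands for shell use. See the methods vignette
(`vignettes/g4-landscape-methods.Rmd`) for the model, parameter and
calibration details.

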