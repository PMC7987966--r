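---
title: "Methods: G-quadruplex landscape annotation and enrichment"
author: "g4scape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: G-quadruplex landscape annotation and enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4scape)
```

## What the package computes

G-quadruplexes (G4) are four-stranded DNA secondary structures formed by
stacked guanine tetrads. Genomic regions able to fold into a G4 can be
predicted from sequence alone: four runs of guanines separated by short
loops. `g4scape` implements the sequence-level side of a G4 ChIP-seq study:

1. **Motif prediction** — a quadparser-style regular-expression scan for
   G4-forming patterns, parameterized by minimum G-run length, loop-length
   range and required run count.
2. **Peak annotation** — fraction of ChIP-seq peaks containing predicted
   motifs, repeat elements (LINE/L1, SINE/Alu, ...), lamina-associated
   domains (LADs), or genomic context features, all under non-exclusive
   membership (a peak counts in every category it touches).
3. **Permutation enrichment** — significance of any such colocalization
   against width-matched, randomly repositioned probe sets.
4. **Condition comparison and expression link** — shared/specific peak
   accounting between two conditions, and exact binomial tests for
   expression-direction bias in peak-associated gene sets against a stated
   baseline upregulated fraction.
5. **Imaging quantifications** — line-profile Pearson colocalization,
   seeded K-means grouping of per-cell intensities, and box-plot summaries.
6. **Synthetic data** — a generator that emulates all of the above inputs
   with planted, recoverable truths.

## The motif model and its matching semantics

A G4 motif is matched by the pattern

```
(G{g,} L{lmin,lmax}) x (k-1)  followed by  G{g,}
```

with `g = g_run_min`, loop `L` any base, and `k = n_runs` required runs.
Matching is case-insensitive, leftmost and greedy, and non-overlapping:
after a match, scanning resumes at the match end. These are exactly the
semantics of a backtracking regular-expression engine run with
`([gG]{g,}\w{lmin,lmax}){k-1,}[gG]{g,}`, which is how such scans are
conventionally scripted; the greedy repetition means a match absorbs as
many additional G-runs as the loop constraint allows, so motif counts are
conservative (clustered runs merge into one motif). One subtle consequence
of backtracking semantics is that a long G-run may be *split* by the
matcher, with part of the run serving as loop sequence; the test suite pins
this behavior against an independent enumerator that replays the greedy
priority order explicitly.

The minus strand is scanned on the reverse complement and mapped back to
forward coordinates, so C-run patterns on the forward strand are reported
as `-` motifs. Default is both strands.

Four presets ship with the package: `canonical`/`preset1` (runs of >= 3 G,
loops 1–12 nt — the most stringent canonical G4 definition), `preset2`
(>= 3 G, loops 1–7) and `preset3` (>= 5 G, loops 1–7). Presets 1–3
approximate published stringency tiers whose exact parameters are not
printed anywhere we can cite them from; they are labeled approximate and
fully configurable through `quadparser_params()`.

**Implementation note.** On chromosome-scale strings the scan first finds
maximal G-runs from raw bytes and clusters runs separated by gaps of at
most `loop_max` non-G bases. A valid match can never contain a longer non-G
stretch, so running the regex once per cluster is provably equivalent to a
global scan and roughly twenty times faster on megabase sequences.

## QGRS-style scoring

For short motif sequences, `qgrs_best_score()` enumerates every four-run
candidate (runs >= 2 G, loops 0–12, possibly splitting longer runs) and
scores each as

```
score = 20 * (t - 2) + sum(loop_max - l_i) - (max(l) - min(l))
```

where `t` is the shortest run length and `l_1..l_3` the loops. The three
terms reward more stacked tetrads, shorter loops, and equal loops — the
ranking criteria QGRS-style scores are built on. The constants are this
package's own; published QGRS tools use unpublished internals, so scores
are comparable within `g4scape` only. Ties resolve leftmost, then
shortest. Enumeration is exhaustive and intended for motif-scale inputs
(tens to a few hundred bases), not chromosomes.

## Interval conventions

Externally, all files follow their community conventions: BED and rmsk
coordinates are 0-based half-open. Internally the package uses
`GenomicRanges`, i.e. 1-based closed ranges, converting at every reader and
writer; BED round-trips are exact, which the suite checks on random sets.
Overlap arithmetic is strand-agnostic (ChIP-seq peaks are unstranded), uses
a 1 bp minimum overlap by default (the common "colocalized" definition),
and half-open/closed bookkeeping is pinned by boundary tests (abutting
intervals never overlap). Peak extension for G4 annotation uses a 50 bp
flank on each side, clamped at chromosome bounds.

## The permutation null

`randomize_regions()` repositions each interval uniformly among all valid
genome positions for its width (chromosome drawn proportional to
`length - width + 1`). Probes may overlap each other and no assembly-gap
mask is applied by default — the null models "randomly positioned probes",
nothing more. The enrichment p-value is the add-one empirical estimator

```
p = (1 + #{null >= observed}) / (n_perm + 1)
```

which can never be exactly zero, together with a z-score
`(observed - null mean) / null sd` (reported as 0 with a degeneracy flag
when the null has zero spread, e.g. a feature covering the whole genome).
Default `n_perm = 1000`. `multi_feature_enrichment()` evaluates all feature
sets against the *same* stream of randomized probe sets, so columns are
directly comparable across features.

Because ties count as extreme and the estimator adds one, the empirical p
is *super-uniform* (conservative) under the null by construction. The
calibration test therefore applies a one-sided Kolmogorov–Smirnov check
against anti-conservatism — `P(p <= t)` must not exceed `t` — rather than a
two-sided uniformity test, which any conservative estimator would
eventually fail for purely structural reasons when the test statistic is
discrete. For the permutation loop the package uses a sorted-endpoint
counting fast path (two `findInterval` calls per chromosome); a property
test pins it to `countOverlaps` on random fixtures, and observed statistics
always go through the public counting path.

## Expression-direction binomial test

Genes are linked to peaks by >= 1 bp overlap with named gene bodies
(unextended). Direction comes from the sign of `log2fc` alone; zero
fold-changes are excluded, and no adjusted-p filter is applied by default
because the analysis treats the volcano-plot superposition as using all
genes (a threshold is configurable upstream of the call). Given a baseline
upregulated fraction `b` (e.g. the 51% genome-wide baseline of a contrast
with 2006 genes up and 1924 down), the test reports both exact one-sided
binomial tails, `P(X <= k_up)` and `P(X >= k_up)` for
`X ~ Bin(n, b)` — the direction of interest is left to the caller since
either reading may be wanted. The tails overlap at `k_up`, so they sum to
at least 1.

## Imaging quantifications

`pearson_profile()` is the standard Pearson correlation of two intensity
vectors measured along the same line profile. `kmeans_cells()` runs Lloyd's
algorithm with k (2 or 3) initial centers sampled from the data rows under
a fixed seed and at most 20 update rounds; `n_start` (default 1) adds
seeded restarts, keeping the run with the lowest within-cluster sum of
squares — single random starts can land in split-cluster local optima, so
group-recovery analyses should raise it. `box_stats()` reports
`min / q25 / mean / q75 / max` with linearly interpolated quartiles; the
center line is deliberately the **mean**, not the median, matching the
plotting convention the quantifications were designed for (on skewed data
the center line may sit outside the box).

## The synthetic study

`sim_spec()` fixes the generator's conditions; defaults are two 2-Mb
chromosomes at GC 0.41 (human-like), 120 planted copies of a synthetic
1.2-kb L1-like consensus carrying three canonical G4 motifs, 40% of copies
conserved (divergence 0) and the rest degraded by per-base substitution at
rate 0.2 (comparable to old L1 subfamilies, and enough to destroy most
planted motifs), 400 peaks of width 600 +/- 150 bp (truncated at 50)
targeting conserved copies with probability 0.9, a LAD map covering half
the genome split 60/40 between constitutive and facultative domains, 5000
genes with a 51% baseline upregulated fraction, and 50 flagged genes
downregulated with probability 0.8. A single global seed fans out to
per-generator streams by fixed offsets, so every artifact is
byte-deterministic given the seed.

Construction details worth knowing:

* The consensus background is C-free (A/C/T filler with G only inside the
  planted runs), so the consensus carries exactly three canonical motifs
  and no incidental reverse-strand motif.
* LAD blocks are carved deterministically, one per 250-kb period, and
  assigned largest-first to whichever side keeps the running cLAD share
  closest to 60% — robust to uneven terminal blocks on small chromosomes.
  Union coverage lands within 2% of target by construction.
* Repeat copies are placed uniformly without overlapping each other, with
  bounded retries; peaks targeting a conserved copy are centered on a
  uniform position inside it.

What the generator does **not** emulate: L1 indels and 5' truncation
gradients, GC isochores, assembly gaps, read-level noise or peak-calling
artifacts, and correlated gene expression. Passing the planted-truth tests
therefore demonstrates that the statistics recover what they are defined to
recover under their own model — not that the pipeline is robust to every
property of real ChIP-seq data.

## Problem sizes and numerical choices

The shipped tests run the motif-scan oracle on 200 random 5-kb sequences
for all presets, overlap counting against a quadratic oracle on 50 random
fixtures, 500 replicate permutation tests at `n_perm = 200` for
calibration, the full default simulation (4 Mb, 1000 permutations) for
planted-truth recovery, and a 100-replicate power check for the planted
down-bias — sizes chosen so the whole suite completes in about two minutes
on one core while keeping Monte-Carlo error well inside the asserted
tolerances. Binomial-test calibration uses random gene subsets of varying
size (200–400), because at any fixed size the discrete atoms of exact
binomial p-values dominate a distributional comparison regardless of how
many resamples are drawn.

## Known limitations

* Motif prediction is pattern-based; no thermodynamic stability model
  (G4Hunter-style scores) and no RNA G4 folding.
* The randomization model is genome-uniform; no GC-matched or
  window-constrained backgrounds.
* Repeat conservation is taken from the annotation (or the generator's
  truth labels), not inferred from divergence columns; `milli_div` is
  carried through for user-side filtering only.
* `qgrs_best_score()` is exponential in G density and meant for short
  sequences.
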