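---
title: "Methods: decomposing developmental transcriptomes and epigenomes"
author: "devdecomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decomposing developmental transcriptomes and epigenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devdecomp)
```

# What the package computes

devdecomp is a desk-scale reimplementation of the analysis layer that sits
between standard quantification output (FPKM/TPM matrices, UMI counts, DHS
peak calls, binned ChIP/ATAC signal, chromatin-state segmentations) and
biological interpretation in a multi-tissue developmental atlas:

1. **Bulk structure** — partition genes into dynamic vs ubiquitous, PCA with
   z-scored sample scores, hierarchical clustering with major-clade
   extraction, canonical correlation against sample metadata, embryo sex
   inference, and stratification of ubiquitous genes.
2. **Single-cell features** — platform-specific QC, library-size
   normalization, dispersion ranking, tight-cluster feature selection,
   one-vs-rest Wilcoxon marker calling, and exclusive-marker derivation.
3. **Epigenomic signal** — conversion of raw binned signal to capped
   −log10 *P* tracks under a locally adjusted negative-binomial background,
   promoter-window fold changes, and de-repression scoring.
4. **cCRE assignment** — merged DHS peaks filtered by chromatin-state class,
   assigned to the nearest expressed TSS, categorized by distance, and
   attributed to cell types through exclusive markers.
5. **Motif graphs** — promoter extraction, PWM scanning with
   shuffled-sequence thresholds, Fisher-based enrichment requiring
   significance under two promoter annotations, and the bipartite
   motif–cluster graph.

A seeded synthetic-data module generates every input with ground-truth
tables, so each stage is scored by parameter recovery rather than by eye.

# Models and key parameters

## Dynamic/ubiquitous partition

A gene is *dynamic* when its max/min abundance ratio across samples is at
least 10 (inclusive), on the linear FPKM scale. Zero minima are floored at
the 0.1 pseudocount — the same pseudocount used in `log_transform()`
(`log2(x + 0.1)`) — so ratios stay finite and the two conventions agree.
The threshold (`fold = 10`) and pseudocount are arguments.

## PCA and CCA

PCA treats samples as observations and genes as variables, gene-centred and
unscaled. Sample scores are z-scored per component; loadings are unit-norm
eigenvectors. Because eigenvector signs are arbitrary, each component is
fixed so its largest-|loading| gene is positive (ties broken by gene id) —
results are then identical across linear-algebra backends.

CCA runs between the top 20 PC score columns and a Boolean metadata design
(one indicator per tissue/stage/sex/batch level, collinear columns dropped
by QR rank). Gene-side loadings of each canonical variate are the PCA
loading matrix times the PC-side canonical coefficients, which maps
metadata axes (sex, dissection batch) back onto genes. With the default
synthetic design (5 tissues × 4 stages × 2 replicates = 40 samples) the
planted sex and batch axes come back with canonical correlations > 0.99.

## Major-clade extraction

Genes are clustered with distance 1 − Pearson *r* and average linkage. The
original procedure split clades by manually recognized dominant tissues and
GO terms; no algorithm exists for that step. The automated stand-in here
traverses from the root and splits a clade into its two children only while
*both* children hold at least `min_clade` (30) leaves; a clade that cannot
be split further is a major cluster. This is label-free (usable on real
data), deterministic, conservative for coherent blocks smaller than
2 × `min_clade` (a tight block is never fragmented), and reduces to the
intuitive answer on planted anti-correlated blocks. Leaves under
sub-threshold branches remain unassigned. "At least 30 nodes" is read as 30
*leaves*.

## Single-cell QC and markers

Full-length (FPKM) QC: cells need ≥ 100,000 transcriptome-mapped reads and
≥ 4,000 genes at ≥ 10 FPKM; genes must be detected in ≥ 5 cells, reach
10 FPKM in some cell, and (when a read-count companion matrix is supplied)
100 mapped reads in some cell. Tag (UMI) QC: cells need ≥ 1,000 and
≤ 8,000 detected genes and ≤ 20% mitochondrial reads; genes must be
detected in ≥ 0.1% of the surviving cells. All stated minima are
inclusive. Chamber-microscopy exclusions (doublets, biased chips) are an
input mask, not computed.

Normalization is `ln(10^4 · x / libsize + 1)` per cell. The natural log is
a deliberate choice — the base only rescales downstream log values — and is
recorded here rather than guessed at by users.

Dispersion is sample variance (n − 1) over mean. Tight-cluster selection
clusters the top 4,000 high-dispersion genes (1 − *r*, average linkage),
cuts the tree at height 0.8, and keeps genes in clusters with **more than
two** members; sporadic high-dispersion genes that co-express with nothing
fall out. Whether dispersion should use raw or normalized values is not
settled for tag data; this package uses normalized values.

Marker calling is one-vs-rest two-sided Wilcoxon rank-sum with normal
approximation and tie correction (no continuity correction), applied to
genes with detection fraction ≥ `min_pct` (0.25) in either group and
|pct_in − pct_out| ≥ `min_diff_pct` (0.2 or 0.4). P values are
Bonferroni-corrected by the total gene count of the matrix (the
conservative convention of the wrapped tool family); fold changes are log2
of de-logged (`expm1`) group means with pseudocount 1. Exclusive markers
are genes marking exactly one cell type, or exactly the member set of a
declared lineage group (e.g. `Muscle1+Muscle2`).

## Negative-binomial P-value tracks

Per sample, the background mean *m* and variance *v* are the moments of the
bin values at or below the empirical 99th percentile (type-7 quantile).
Note an intrinsic property of this estimator: trimming the top 1% of a
heavy-tailed NB shrinks the variance substantially (about 18% at
*m* = 5, *v* = 20) while barely moving the mean; the fitted moments target
the trimmed distribution, not the raw one, and the tests score them against
exactly that quantity.

The NB is parameterized by moments: size *r* = *m*²/(*v* − *m*), with a
Poisson fallback when *v* ≤ *m*. Local genomic variation is absorbed by
20-kb centred rolling means of signal and input (truncated at chromosome
ends, not padded): their per-bin ratio (1 where the input rolling mean is
0 — no information, no adjustment) is normalized to genome-wide mean 1 and
scales the background mean only; the variance is rescaled to preserve
*v*/*m*. Each bin value *x* (floored if fractional) becomes
−log10 *P*(X ≥ *x*) — upper tail inclusive, the standard enrichment
convention — computed in log space (`pnbinom(..., log.p = TRUE)`) so the
cap at 16 is exact even where the tail underflows a double. Default bin
width is 200 bp, configurable.

## cCRE assignment

DHS peaks are merged as a coalesced union; bookended intervals (gap 0)
merge. Peaks survive only if they overlap, by ≥ 1 bp in any segmentation
sample, a whitelisted state: active (14, 19, 20, 21, 23, 24, 25, 27, 28,
30–32), poised (8, 13) or bivalent (26, 29). When classes conflict across
overlaps, the single recorded label follows active > bivalent > poised.
A gene is expressed when its bulk maximum exceeds 0.1 FPKM or it is
detected in more than four single cells. Peak-to-TSS distance is 0 when
the TSS lies within the peak and otherwise the gap to the nearer interval
edge (a bookended TSS is at distance 0); nearest-TSS ties break by gene
id. Categories: ≤ 200 bp proximal, 201–2,000 bp middle, > 2,000 bp distal,
inclusive on both stated boundaries. Elements assigned to exclusive-marker
genes inherit that cell type; others stay in the full cCRE table only.

## Motif enrichment

Promoters are the 500 bp upstream of each TSS (strand-aware, truncated at
chromosome ends). Scanning is a both-strand log-odds scan against a
uniform background, probabilities floored at 1e-4; a sequence is a hit if
its best window reaches the 0.999 quantile of best scores on
mononucleotide-shuffled copies (seeded, reproducible). Enrichment is a
one-sided Fisher exact test of foreground vs background hit counts
(foreground ⊆ background), Bonferroni-corrected over the motif library;
this is a fully specified, oracle-testable substitute for the AME scoring
used historically, whose internal statistic is not reproducible from its
description. A motif is significant only when its corrected *P* < 0.01
under **both** promoter annotations supplied (two TSS tables; the
synthetic tests perturb TSSs by ±50 bp to emulate annotation variants).
PWM columns off unit mass by ≤ 1e-3 are renormalized (published matrices
round); larger deviations are treated as corrupt files.

# The synthetic data: what it emulates, what it does not

All generators are pure functions of a config whose single seed fans out to
fixed per-generator child streams. Defaults: 5 tissues × 4 stages × 2
replicates and 2,000 genes (bulk); 5 cell types × 200 cells with 10
exclusive markers per type at detection 0.9 vs 0.05 and 4-fold mean change,
a 10-gene co-expression module, 50 independent high-dispersion noise genes
(single-cell); a 2-chromosome ~2 Mb genome with 20-kb-spaced TSSs, 50
planted enhancers at 100 bp / 1 kb / 5 kb from marker TSSs on rotating
active/poised/bivalent states, 30 decoy peaks on non-whitelisted states,
and NB(5, 20) signal with 8× elevated means over elements. These sizes
keep every oracle comparison and the full test suite in well under a
minute per stage while leaving all decision boundaries exercised.

Bulk noise is bounded (±0.15 in natural log), not log-normal, so planted
fold-ratio guarantees are exact for every seed — dynamic blocks cannot
drift below threshold and ubiquitous genes cannot drift above it. That is
a deliberate property of the truth tables, not a claim about biology.

What the generators do **not** emulate: realistic sequence composition or
read-level error, gene length and GC effects on abundance, ambient RNA and
doublets, overlapping or nested regulatory elements, replication-timing
or copy-number structure in the signal, and annotation errors beyond the
±50 bp TSS perturbation. Passing tests therefore demonstrate algorithmic
correctness against the stated rules, calibration of the statistics under
their assumed models, and end-to-end bookkeeping — not robustness to every
artefact of real data.

# Numerical choices and degenerate inputs

- Ties anywhere a ranking matters (loadings, nearest TSS, dispersion,
  cluster ordering) break by lexicographic gene id.
- Constant genes get correlation-distance 1 to everything, with a warning;
  zero-variance Wilcoxon comparisons return *P* = 1.
- `stratify_ubiquitous` removes genes whose *mean* log2(FPKM + 0.1) is no
  higher than 2 (the flat ubiquitous profile makes mean vs max nearly
  equivalent); with fewer than `n` eligible genes it uses all of them and
  warns.
- Promoter and TSS windows running off a chromosome truncate with a
  warning; a TSS off the chromosome is an error.
- bedGraph intervals must align to the declared bin grid; misaligned
  intervals name the offending record. Readers/writers round-trip
  losslessly, with equal-value runs compressed to single intervals.
- All coordinates package-wide are 0-based half-open, asserted at every
  boundary.

# Known limitations

- The major-clade rule can merge two correlated sub-programmes whose joint
  clade never splits into two ≥ 30-leaf children; the manual procedure it
  replaces could separate them by annotation.
- Fisher-on-hits enrichment discards within-sequence hit multiplicity and
  rank information; it is calibrated but less sensitive than scoring-based
  methods for weak motifs.
- The NB background is fit genome-wide per sample; chromosome-specific
  backgrounds (e.g. sex chromosomes) are only captured through the local
  rolling-mean adjustment.
- `qc_filter_full_length`'s read-count gene rule requires the companion
  read matrix; without it only the FPKM-based rules apply.

# Session

```{r}
sessionInfo()
```
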