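---
title: "Methods: detecting a mutant stage delay in anther transcriptomes"
author: "anthersom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting a mutant stage delay in anther transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anthersom)
```

## The scientific problem

Rice anthers pass through a tightly staged developmental program — tetrad
(ST8), early uninucleate (ST9), late uninucleate early and late (ST10E,
ST10L), bicellular (ST11) — during which the tapetum, the innermost anther
cell layer, degenerates by programmed cell death to feed the maturing
pollen. In autophagy-deficient mutants this degeneration is retarded, and
the transcriptome looks as if the whole stage program runs late: the mutant
at a given stage resembles the wild type one stage earlier.

`anthersom` implements the complete analysis chain used to make that
delay claim quantitative from bulk RNA-seq of staged anthers in two
genotypes (wild type and mutant, three biological replicates per
genotype-stage cell, 30 samples in all), together with a simulator that
generates data with a *known* one-stage delay so every step of the chain
can be validated against ground truth.

## The analysis chain

### Normalization and QC

Counts are normalized with the trimmed mean of M-values (TMM): the
reference sample is the one whose upper-quartile CPM is closest to the
mean upper-quartile; for every sample the gene-wise log2 ratios (M)
against the reference are doubly trimmed — 30% on each side by M, 5% on
each side by A (average log abundance), genes with a zero in either
sample excluded — and averaged with precision weights (inverse asymptotic
variance of M); factors are rescaled to geometric mean 1. CPM uses the
effective library size (library size times factor); log2-CPM adds a
prior count (default 0.5) scaled by relative library size so values stay
comparable across sequencing depths.

Sample-level QC comprises a Pearson correlation matrix of log2-CPM, and
multidimensional scaling where the distance between two samples is the
root-mean-square of their 500 largest absolute log fold changes
(pairwise gene selection) embedded by classical metric scaling.

### Differential expression

Gene-wise negative-binomial GLMs with log link and log effective library
sizes as offsets are fitted by Fisher-scoring IRLS (convergence at
relative deviance change below 1e-8, at most 50 iterations; fitted means
floored at 1e-8 so all-zero genes stay finite; with dispersion 0 the
model reduces exactly to Poisson regression). Dispersions are estimated
by Cox–Reid adjusted profile likelihood (APL) on a 61-point log grid
over [1e-6, 10] with quadratic interpolation at the maximum: the common
value maximizes the APL pooled over genes, and tagwise values maximize
each gene's APL after weighted shrinkage toward the pooled average with
prior weight `prior_df / residual df` (prior_df = 10, chosen to
stabilize three-replicate designs). Nested models are compared by
likelihood-ratio tests against a chi-square reference, and p-values are
BH-adjusted.

Two DEG classes are defined:

* **stage/genotype-dependent genes (ASDs)** — BH FDR < 0.01 in either
  single-factor test (stage vs intercept, genotype vs intercept); a
  joint-model alternative (genotype+stage vs intercept) is available via
  `asd_mode = "joint"`. The union default reflects the wording
  "either ... or ... as factors" of the study design being emulated;
  both parameterizations are exposed because the original description is
  ambiguous.
* **genotype-dependent genes (ADDs)** — BH FDR < 0.05 in any per-stage
  mutant-vs-WT contrast, taken from a one-way genotype-by-stage
  parameterization (one coefficient per cell; the reduced model merges
  the two cells of the tested stage). Per-stage "two-fold up/down"
  flags additionally require |log2FC| at or above 1, with log2FC computed
  from coefficient differences (fitted, not raw, fold changes — raw
  ratios are undefined for zero-count groups; the fitted-mean floor
  handles those).

### SOM clustering and the displacement network

Stage profiles (mean log2-CPM over the three replicates, per genotype)
are scaled per gene in one of two modes: *per-genotype z* (centered and
scaled within each genotype separately, so both genotypes become
comparable pure shapes) or *wt-referenced* (the mutant profile centered
and scaled by the wild-type mean and SD, preserving mutant deviations
from the WT program). Zero-SD genes are dropped and counted.

A batch Kohonen SOM on a rectangular grid (4 x 4 for the
stage-dependent set, 3 x 3 for the genotype-dependent set; units indexed
row-major) is trained for 100 iterations: each iteration assigns every
vector to its nearest prototype and replaces each prototype by the
Gaussian-weighted mean of all vectors, the neighborhood truncated at the
current radius, which decays linearly from max(rows, cols)/2 to 0.5.
The truncation means training ends with every unit refining on its own
members alone (k-means-like), which makes prototypes converge onto
cluster centroids and keeps the final quantization error below the
initial one. Initialization is deterministic (a regular grid spanned by
the first two principal axes of the data); seeded sampling of data
points is available. Batch rather than online training was chosen so a
fixed initialization gives bit-reproducible maps. The 4 x 4 map is
trained on the union of WT-scaled and mutant-scaled vectors so both
genotypes share one map — required for cross-genotype comparability of
cluster labels in the displacement analysis.

A gene is **displaced** when its WT vector and mutant vector win
different units and both distances are strictly below 0.8 (scaled-space
Euclidean; the filter is configurable to apply to one genotype only —
both-sided application is the conservative default). Displaced genes
aggregate into a directed WT-cluster to mutant-cluster network whose
edges carry gene counts and percentages of all displaced genes.

The **delay score** makes the delay reading of this network explicit:
each prototype is shifted one stage later (the same construction the
simulator uses), re-assigned to the map, and the resulting
cluster-successor map is compared with the displacement edges. The score
is the fraction of displaced genes that moved exactly to their WT
cluster's successor. Clusters whose shifted prototype wins its own unit
carry no delay information (a displaced gene can never land "in place"),
so their genes leave the denominator.

### Enrichment, ordination, qPCR

Term enrichment is a hypergeometric upper-tail test per term
(p = P[X >= hits]), BH-corrected within each query set, on a flat
annotation (no term-hierarchy propagation — the synthetic annotations
are flat, and hierarchy handling belongs to dedicated GO tooling). The
default universe is the gene set entering the respective analysis (for
displacement enrichment, the clustered stage-dependent genes), not the
whole genome.

PCA treats samples as observations and genes as variables (centering,
no scaling), computed by SVD; component signs are fixed by forcing each
component's largest-magnitude loading positive so results are
reproducible. The log2FC heatmap matrix extracts the fitted per-stage
mutant-vs-WT fold change for the genotype-dependent genes, rows ordered
by average-linkage hierarchical clustering.

qPCR quantification uses the 2^-ddCt convention: per replicate,
dCt = Ct(target) - Ct(reference) within a sample; ddCt subtracts the
mean dCt of the calibrator condition (WT at ST8); condition summaries
exponentiate the mean ddCt (geometric handling — the calibrator then
evaluates to exactly 1), with the arithmetic alternative exposed as an
option. Amplification efficiency is fixed at 2.

## The simulator and what it does (not) emulate

`generate_programs()` draws, per gene: an archetypal stage shape
(monotone up, monotone down, a transient peak at each of the five
stages, or flat), a log-normal baseline mean (median 50 counts), a
log-normal NB dispersion (median 0.1), a log2 amplitude in [1, 3], and
the two mutant effects — a one-stage delay (default 30% of genes) and/or
a constant log2 level shift (default 10%, magnitude 0.5–1.5). Flat
unshifted genes (default 20%) are nulls. Class sizes are deterministic
quotas, so requested fractions are met exactly. The delay is a
right-shift with the boundary value held (`mut[s] = wt[s-1]`,
`mut[ST8] = wt[ST8]`): development has no periodicity, so nothing wraps
around, and the mutant's first stage still matches the wild type —
consistent with the biology, where the earliest stage is least affected.

Archetype weights are deliberately non-uniform (peaks weighted
0.05/0.15/0.30/0.05/0.15 across the five stages; up/down 0.15 each):
transcriptional turnover in this system concentrates at the
mid-uninucleate transition, and the weighting gives the simulated delay
phenotype a well-defined stage of maximal genotype separation (ST10E
under the defaults). That stage is always *computed* from the programs
(`max_separation_stage()`), never assumed.

`simulate_counts()` draws NB counts with mean
`L_s * q_g / sum(q)` where `L_s` is a log-normal library size (median
5e6, log-SD 0.2) — so the data are compositional, exactly as sequencing
data are — and per-gene dispersion; dispersion-zero genes are Poisson.
Replicate noise enters only through NB sampling, matching the NB-GLM
assumed downstream; there are no batch effects, no isoforms, no
read-level simulation. Passing tests on these data therefore shows the
chain is correct and calibrated *under its own model*; it does not show
robustness to violations (outlier samples, batch structure,
length-biased counting) that real data may carry.

`generate_annotation()` plants known-enriched terms by weighted
sampling (odds ratio 5 toward delayed genes; default 100 terms of 50
genes, 5% of terms enriched), and `generate_ct_table()` writes Ct values
with `Ct(target) - Ct(ref) = -log2(expression) + noise`, so ddCt
round-trips are exact at zero noise.

## Numerical choices and degenerate inputs

* IRLS starts at `mu = y + 0.1 * (mean(y) + 1)`; linear predictors are
  clamped to [-50, 50]; fitted means floored at 1e-8.
* LRT statistics in [-1e-6, 0] are clamped to 0 (floating-point noise);
  larger negatives are reported as NA with a warning — they indicate a
  convergence failure, not evidence.
* Assignment ties (equidistant prototypes) go to the lowest unit index;
  TMM reference ties go to the lowest sample index; top-edge ties order
  lexicographically by (WT cluster, mutant cluster).
* A SOM unit with no weight in an iteration keeps its previous
  prototype; zero-variance genes are excluded from scaling (with a
  count); all-zero genes are excluded before DEG testing; an all-zero
  *sample* is a hard error naming the sample.
* Genes whose total CPM over all 30 samples is exactly at the filter
  threshold are removed (the filter is strict).

## Reproducibility

Every stochastic function takes an explicit seed; the pipeline derives
per-stage seeds from one master seed and records an MD5 checksum per
output plus a hash of the analysis configuration in `manifest.json`.
The manifest deliberately carries no wall-clock timestamps so that two
runs from the same seed produce byte-identical manifests; rerunning over
intact outputs with `force = FALSE` does nothing.

## Problem sizes

The package's own validation runs at desk scale, chosen so the full
suite completes in minutes on one core while every statistical check
retains power: 2,000-gene simulations for null calibration (type-I
error, FDR control, dispersion recovery), 4,000–6,000-gene runs for the
end-to-end delay-recovery and SOM-occupancy checks, and 700-gene runs
for pipeline determinism. The simulator's scientific defaults
(`n_genes = 20000`, 30 samples) match the scale of a real anther
transcriptome and are what `run_pipeline()` uses unless told otherwise.

## Known limitations

* The NB-GLM uses chi-square asymptotics for the LRT; with three
  replicates per cell this is mildly liberal, which the type-I
  calibration bounds (0.035–0.065 at nominal 0.05) make visible rather
  than hide.
* Dispersion shrinkage uses a fixed prior (10 residual df) and no
  mean-dispersion trend; quasi-likelihood F-tests and exact tests are
  out of scope.
* The SOM is rectangular and non-toroidal only; no growing or
  hierarchical variants. "Multilevel" clustering here means the two
  grid sizes (4 x 4 and 3 x 3), not a hierarchy of maps.
* Enrichment treats annotation as flat; no GO DAG parsing or
  parent-term propagation.
* ddCt assumes perfect doubling per cycle; efficiency-corrected
  (standard-curve) quantification is out of scope.
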