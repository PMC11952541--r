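---
title: "Methods: region-resolved small-RNA aging analysis with mirage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-resolved small-RNA aging analysis with mirage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirage)
```

## The analysis problem

Bulk small-RNA sequencing of many brain regions across the lifespan
produces a count matrix (features × samples) together with sample
metadata (region, age in months, sex, individual, aligned-read counts)
and a feature annotation (RNA class, genomic interval, strand, isomiR
links). The questions such an atlas answers are: which features mark a
region, which change with age and where, whether the sexes age alike,
how aging trajectories group across regions, whether age-correlated
miRNAs cluster on the genome, and whether candidate regulators
anti-correlate with their mRNA targets. `mirage` implements that chain
of analyses as composable functions plus an orchestrating
`run_pipeline()`, and ships a synthetic-cohort generator so the whole
chain can be validated against planted ground truth.

## Quality control and normalization

- **Sample filter** (`filter_samples`): keep a sample only if *strictly
  more* than `min_aligned_reads` reads aligned (default 2,000,000; a
  sample at exactly the threshold is dropped). For intervention-style
  cohorts an additional rule discards every region left with
  `min_region_samples` (default 3) surviving samples or fewer. Presets:
  microglia 1.8 M reads; human cohorts 10,000 reads.
- **Feature filter** (`filter_features`): a feature is retained iff in
  at least one group (regions by default, sexes for the human preset)
  the fraction of samples with raw count ≥ `min_count` (default 5;
  human preset 2) reaches `min_fraction` (default 0.10). Both
  thresholds are inclusive and the fraction is compared exactly, so 1
  of 10 samples passes 10%. The same inclusive rule defines "expressed
  in a region" (`expressed_in_region`).
- **rpmm normalization** (`rpmm`): counts are scaled to reads per
  million mapped to the feature's own RNA class per sample (for miRNAs,
  the sample's miRNA total), the convention of small-RNA quantifiers.
  The denominator is configurable to the global per-sample total, and
  isomiR tables are normalized with their archetype class's denominator
  so archetype/isomiR ratios are meaningful. A zero denominator is an
  error naming the sample.
- **Standardization** (`zscore`): population standard deviation
  (divisor *n*) throughout; zero-variance slices are emitted as zeros
  with a `degenerate` flag instead of NaN.

## Variance structure (PVCA)

`pvca()` standardizes features, runs a PCA over samples, and retains
the leading components up to a cumulative-variance threshold (default
0.9). Each retained component's scores are decomposed by a
random-intercept REML model (lme4) with every factor and every two-way
interaction as random effects. Per-factor proportions are then weighted
by each component's share of the **total** variance and summed, with
the variance of unretained components attributed to the residual.

This weighting is a deliberate design choice. Normalizing over retained
components only — the more common presentation — inflates structured
shares because retention enriches for structure: in a simulation where
a region effect contributes exactly half the variance, retained-only
normalization at a 0.6 threshold reports roughly two thirds, while the
total-variance weighting reports 0.50 ± 0.03. The calibrated variant
makes the shares interpretable as fractions of observed variance, which
is how they are used (a diagnostic of which metadata factors matter,
not a batch correction). Singular or failed REML fits fall back to a
sequential non-negative attribution with a warning.

## Region signatures

`region_signatures()` selects the top `k` (default 50) features by the
coefficient of variation of their per-region medians (sd/mean; ties
broken lexicographically by feature id, zero-mean features excluded
with a warning), z-scores the region medians per feature, and calls a
feature *different from the brain average* in a region when |z| ≥ 0.5
(inclusive). The binarized profiles are clustered over regions by
complete-linkage hierarchical clustering cut at four clusters.
Euclidean distance on the 0/1 vectors is the default (it orders pairs
identically to Hamming distance); Hamming and Jaccard are selectable.
A feature exceeding the threshold in exactly one region is
*brain-region specific*. `compare_sex_signatures()` classifies features
shared between the sexes, including the same-single-region and
same-multi-region-set categories.

## Differential expression

`de_analysis()` computes per (feature, stratum): a fold change of group
centers, a two-sided Welch *t* p-value, Benjamini–Hochberg adjustment
within the stratum's retained features, and significance flags
(padj < 0.05 together with FC ≥ 1.5 up, FC ≤ 1/1.5 down). Choices worth
stating:

- **Centers.** The sex contrast uses a geometric mean with pseudocount
  (default 0.5 rpmm) — the robust multiplicative center that stays
  defined with zeros; the old-vs-young age ladder (`de_age_ladder`)
  uses plain medians; the human effect-size preset uses the geometric
  mean and adds Cohen's d (pooled SD on nA+nB−2 df) with an
  |d| ≥ 0.5 flag. All centers are selectable everywhere.
- **fc = 1 features** are removed before adjustment (they carry no
  deregulation signal and would only inflate the family size);
  zero-denominator fold changes are reported as `Inf` and never
  flagged significant.
- **Tests run on rpmm values** (not logs); a Welch test is invariant to
  neither choice, and the untransformed scale matches the fold-change
  definition used for the flags.
- Degenerate zero-variance groups resolve explicitly: equal means give
  p = 1, unequal constant groups give p = 0.
- `bin_ages()` implements the half-open human age bins \[71,81),
  \[81,92), \[92,103); ages outside every bin are excluded with a
  warning.
- `rank_for_gsea()` exports a single ranked list running from
  strongest-negative to strongest-positive effect (most significant at
  the extremes, unsigned features mid-list, ties broken by id) for
  external enrichment tools.

## Age correlation and candidates

`age_correlation()` correlates each feature with age in months
(Spearman) per region, optionally per sex, adjusts by BH within each
(region, split) family — the per-region family matches the per-region
phrasing of the screening — and flags significance at padj < 0.05 with
rho **strictly** greater than 0.5 (or less than −0.5). The p-value uses
the t approximation on n − 2 df, documented and tested against an exact
permutation p (available for n ≤ 8). Strata are skipped unless at least
two distinct ages carry two or more samples each — the rule that
generalizes excluding sparsely sampled old-female regions.

A feature is *unique* (per direction) when significant in exactly one
region, *multiple* for more than one. `build_candidates()` unions
correlation evidence with the age-ladder DE evidence; a feature whose
direction flips between regions still counts once.

## Trajectory clustering

`build_trajectories()` summarizes each (feature, region) per age stage
(median by default) and z-scores across ages, producing |features| ×
|regions| trajectories (1,174 × 15 = 17,610 at atlas scale). Constant
trajectories and regions with fewer than three age stages are flagged
and excluded from clustering; trajectories with missing age cells are
excluded rather than imputed.

`fuzzy_cmeans()` is the standard fuzzy c-means alternation (fuzzifier
m = 2, Euclidean distance on the z-trajectories): memberships
u ∝ d^(−2/(m−1)), centroids the u^m-weighted means. Initialization uses
distance-weighted (kmeans++-style) sampling of k trajectories with
`nstart = 3` restarts, keeping the lowest final objective — plain
random starts visibly fall into local minima on template-structured
data. The per-iteration objective is recorded (and asserted
non-increasing in tests); after convergence centroids are recomputed
once from the final memberships so each centroid equals the
membership-weighted mean exactly. `select_k()` emits the minimum
pairwise centroid distance over a k range (an mfuzz-style Dmin
diagnostic, our interpretation of "minimum centroid measurement") with
an elbow suggestion that is never applied silently; k remains a user
choice. Hard assignment takes the maximum membership and discards
trajectories strictly below 15%; clusters are *region specific* when
≥ 30% of members share one region, *feature specific* at ≥ 4
occurrences of one feature; singleton clusters are excluded from
evaluation.

## Genomic neighborhood

`neighbor_counts()` counts, for every significantly age-correlated
feature, the other significant features within a 10 kb window on the
same and the opposite strand, per region, accumulating (same, opposite)
tuple occurrences across regions; `baseline_neighbors()` gives the
genome-wide expectation over all annotated features. Distance is the
number of intervening bases between interval edges (overlap counts as
0) and the boundary is inclusive: a 10,000-base gap is inside the
window, 10,001 is outside. Windows anchor on the annotated precursor
interval. `cumulative_coordinates()` concatenates chromosomes for
genome-wide plots.

## Integration

`target_anticorrelation()` correlates target genes with their regulator
miRNA per region (Spearman; monotone-invariant, so the mRNA scale needs
no transform), adjusts across the whole gene × region family of one
miRNA, and tiers hits: anti-correlated at rho ≤ −0.3, strongly
(functionally validated tier) at rho < −0.5, both with padj < 0.05.
Genes missing from the mRNA matrix are reported, not fatal.
`isomir_profiles()` computes per-(region, age) median trajectories for
an archetype and its isomiRs, the archetype share
archetype/(archetype + Σ isomiRs), the top-expressed isomiRs, and a
complete-linkage clustering of regions on mean standardized isomiR
expression cut at three clusters.

## The synthetic cohort generator

`sim_config()` defaults encode the atlas design: 15 regions, age
stages 3, 12, 15, 18, 21, 26, 28 months, two sexes, five samples per
(region, age, sex) cell, 1,174 features, and ~2% of samples below the
2-million-read threshold. Counts are gamma-Poisson (negative binomial,
shared dispersion 0.15 — a typical bulk small-RNA value; the dispersion
is a free parameter of the model, chosen once) around
library-size-scaled softmax abundances with lognormal baseline log2
means (mean 5, sd 2) and lognormal depths (CV 0.25). Aligned-read
metadata is simulated independently of the counts, since QC reads it
from metadata only.

Planted effects act as log2 offsets on expected expression: region
signatures and sex effects are constant offsets; aging trajectories
come in three shapes — *linear* (monotone in age rank), *step* (offset
from an onset age onward, emulating a mid-life jump), *peak* (offset at
one age). Linear magnitudes are specified as a target Spearman
correlation and converted to a signal amplitude via the delta-method
counting-noise sd on the log2 scale (sd ≈ sqrt(1/μ + φ)/ln 2), so the
realized correlation matches the target within sampling error.
Effect-size calibration constants are the implementer's choice and are
validated by recovery tests, not matched to any external dataset.
Genomic coordinates are laid out in clusters (members 5 kb apart,
clusters 50 kb apart, strands flipped with probability 0.25) so both
populated and empty neighborhoods exist by construction. isomiR
families split 1 − archetype_fraction (default 0.3) of the archetype's
expectation across variants. Linked mRNA targets follow a Gaussian
copula: gene = coupling × z(miRNA) + sqrt(1 − coupling²) × noise per
region, so the coupling is the population correlation and −1 with zero
noise is exact.

What the generator does **not** emulate: read-level data, sequence
content, spatially correlated dissection artifacts, batch structure,
heavy-tailed outlier samples, or realistic gene–gene correlation. Tests
passing on these cohorts therefore validate the statistical machinery
and threshold logic — not robustness to every artifact of real
libraries.

## Validation scale and numerical choices

The shipped tests validate recovery at these sizes: age correlation on
500 features × 1,050 samples with 30 planted features over 20 seeds;
DE calibration on 200 features over 20 seeds; template clustering with
4 templates, σ = 0.3 noise, 160 trajectories, 20 seeds (adjusted Rand
index ≥ 0.8); PVCA with a planted 50% region effect over 10 seeds
(±10 points); target recovery with five −0.8 couplings over 20 seeds.
The full trajectory identity (17,610) is checked at atlas scale.

Numerical conventions: population sd in all z-scores; BH via the exact
step-up formula (tested against a brute-force min-tail oracle);
Spearman p via the t approximation (exact permutation p for n ≤ 8);
pseudocount 0.5 rpmm in geometric centers; inclusive thresholds
exactly as stated above; every stochastic step is seeded and the
pipeline manifest records md5 hashes so reruns are byte-identical.

## Known limitations

- PVCA shares depend on the retention threshold; the default 0.9 with
  total-variance weighting is calibrated for recovery, but very
  low-variance factors can still be absorbed by the residual.
- The c-means k is a user choice; `select_k()` is a diagnostic, not an
  estimator.
- The human preset implements binning, centers and effect sizes, but
  no cohort-specific covariate adjustment (the screening is
  deliberately simple).
- Welch tests on rpmm values inherit rpmm's compositional coupling
  between features; strongly deregulated high-abundance features can
  shift others' apparent levels.
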