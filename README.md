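# mirage

Region-resolved small-RNA brain aging atlas analysis in R.

Bulk small-RNA sequencing atlases sample many brain regions across age
stages and both sexes, yielding a raw count matrix (miRNAs and other
small-RNA classes × samples), per-sample metadata and a genomic
annotation. `mirage` implements the full analysis chain for such data,
for researchers studying regional and sex-resolved transcriptomic
aging:

- **QC / ingest** — sample filter on aligned reads (strict > 2 M
  default, with microglia/intervention/human presets), feature filter
  (count ≥ 5 in ≥ 10 % of one region's samples, inclusive), RNA-class
  composition with cubic age trends.
- **Normalization** — rpmm (reads per million mapped to the feature's
  RNA class per sample) and population-SD z-scoring.
- **Variance structure** — principal variance component analysis:
  PCA, then per-component REML variance decomposition over metadata
  factors and two-way interactions, weighted by each component's share
  of total variance.
- **Region signatures** — top-50 features by CV of region medians,
  |z| ≥ 0.5 binarization against the brain average, complete-linkage
  clustering of regions into four clusters, male/female comparison.
- **Differential expression** — fold changes of group centers
  (geometric mean or median), Welch *t*, Benjamini–Hochberg, FC ≥ 1.5
  and padj < 0.05 flags; old-vs-young age ladders; half-open human age
  bins with Cohen's d screening; ranked-list export for enrichment
  tools.
- **Age association** — region-wise Spearman correlation with age,
  BH per region, |rho| > 0.5 strict significance, unique/multiple
  classification, candidate aggregation with DE evidence, external
  list intersection.
- **Trajectories** — per-(feature, region) standardized age
  trajectories, fuzzy c-means clustering (m = 2, seeded kmeans++-style
  initialization), 15 % membership filter, 30 % region-specificity and
  4-occurrence feature-specificity rules.
- **Genomics** — strand-aware ±10 kb neighborhood counts of
  age-correlated features (inclusive boundary, GFF3 I/O via
  rtracklayer), genome-wide cumulative coordinates.
- **Integration** — miRNA–mRNA target anti-correlation (tiers at
  rho ≤ −0.3 and rho < −0.5), isomiR/archetype profiling.
- **Synthetic cohorts** — a generator with negative-binomial counts
  and planted region, sex, aging, isomiR, genomic-cluster and
  target-coupling effects, so the whole pipeline is validated against
  known ground truth with no external download.

## Worked example

Simulate a six-region cohort with one planted aging miRNA and one
planted sex effect, run QC, normalize, and screen:

```r
library(mirage)

cfg <- sim_config(
  n_features = 200, regions = atlas_regions()[1:6], n_per_group = 5,
  planted_age_effects = list(
    list(feature = 1, regions = atlas_regions()[1:6],
         shape = "linear", magnitude = 0.9)),
  planted_sex_effects = list(
    list(feature = 2, regions = "corpus_callosum", log2_offset = 2)),
  seed = 42)

meta <- generate_metadata(cfg)
gen  <- generate_counts(meta, cfg)
qc   <- filter_samples(gen$counts, meta)
print(qc$qc)
#> QC report (sample_filter): kept 410 of 420 (97.6%)
#>   thresholds: min_aligned_reads=2e+06

norm <- rpmm(filter_features(qc$counts, qc$meta$region)$counts,
             gen$rna_class)
corr <- age_correlation(norm, qc$meta, split = "none")
corr[corr$feature == "mir-0001", c("region", "rho", "padj", "significant_pos")]
#>                 region   rho     padj significant_pos
#>        corpus_callosum 0.919 4.77e-26            TRUE
#>         choroid_plexus 0.883 4.50e-21            TRUE
#>                    svz 0.920 3.24e-26            TRUE
#>   hippocampus_anterior 0.895 2.69e-23            TRUE
#>  hippocampus_posterior 0.886 4.51e-21            TRUE
#>           hypothalamus 0.915 8.30e-26            TRUE
```

The planted feature (target Spearman 0.9) is recovered in all six
regions with rho 0.88–0.92 and is classified as a `multiple`-region
candidate:

```r
lab <- classify_correlation_uniqueness(corr)
lab[lab$feature == "mir-0001", ]
#>   feature direction n_regions    label
#>  mir-0001       pos         6 multiple
```

The planted 4-fold sex effect surfaces in the sex contrast in its
planted region only (fold change ≈ 3.7, consistent with the log2
offset of 2 plus counting noise):

```r
rec <- de_analysis(norm, qc$meta, "sex", "M", "F")
rec[rec$significant_up & rec$feature == "mir-0002",
    c("feature", "stratum", "fc", "padj")]
#>   feature         stratum   fc     padj
#>  mir-0002 corpus_callosum 3.72 2.58e-07
```

Trajectories count |features| × |regions| by construction:

```r
build_trajectories(norm, qc$meta)
#> trajectory_set: 1200 trajectories (200 features x 6 regions), 7 age stages
#>   clusterable: 1200, degenerate: 0
```

`simulate_dataset()` writes a complete cohort (counts, metadata, GFF3,
isomiRs, mRNA, links, ground truth) to disk, and `run_pipeline()`
executes every stage from a `pipeline_config()` with a manifest of md5
hashes; reruns with the same seed are byte-identical.

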