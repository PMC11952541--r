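Package: mirage
Title: Region-Resolved Small-RNA Brain Aging Atlas Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for region-, age- and sex-resolved small RNA
    sequencing atlases of the mammalian brain. Covers raw-count quality
    control, reads-per-million-mapped normalization, principal variance
    component analysis, coefficient-of-variation region signatures,
    Welch/Benjamini-Hochberg differential expression, region-wise Spearman
    age-correlation screening, fuzzy c-means trajectory clustering,
    strand-aware genomic neighborhood counts, isomiR profiling and
    miRNA-mRNA target anti-correlation. Includes a synthetic-cohort
    generator with planted region, sex and aging effects so the full
    pipeline can be exercised and validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    lme4,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    e1071,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
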