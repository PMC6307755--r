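Package: meqtm
Title: Integrative Differential Methylation and Expression Analysis with
    eQTM Permutation Testing
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for integrative analysis of DNA methylation arrays
    and RNA-seq counts in small clinical cohorts, built around intestinal
    fibroblast studies of fibro-stenotic Crohn's disease. Provides
    covariate-adjusted differential methylation at position (moderated
    t with patient blocking via pooled-correlation generalized least
    squares) and region level (gap-based clustering with signed Stouffer
    combination and Benjamini-Hochberg control), negative-binomial
    differential expression, intersection of differentially methylated and
    expressed genes, and an eQTM statistic: the Pearson correlation between
    per-region mean methylation and log expression, with percentile
    bootstrap confidence intervals and a permutation p-value from
    CpG-count-matched null regions. A synthetic-cohort generator with
    planted regional methylation effects, fold changes, and
    methylation-expression couplings provides ground truth for every stage.
    Also includes epigenetic-clock age imputation and chromosome-Y-based
    sex inference for anonymized samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    DESeq2,
    S4Vectors
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
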