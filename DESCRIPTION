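Package: plateletPSO
Title: Binary Particle Swarm Feature Selection for Tumor-Educated Platelet
    RNA Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building liquid-biopsy classifiers from blood platelet
    RNA-seq count data. Implements preprocessing of a gene-by-sample count
    matrix (low-count filtering, median-of-ratios size factors, closed-form
    negative-binomial variance-stabilizing transformation, age-correlation
    gene exclusion, surrogate-variable removal), wrapper feature selection by
    binary particle swarm optimization with a cross-validated SVM-AUROC
    fitness, and a classifier-evaluation suite (ROC curves with DeLong
    intervals and comparison tests, Hand-Till multiclass AUROC, confusion
    metrics with exact Clopper-Pearson intervals, leave-one-out
    cross-validation, per-stage sensitivities). A synthetic cohort generator
    with negative-binomial counts, planted class signal, age confounding and
    latent batch structure makes the whole pipeline testable without access
    to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    DESeq2,
    sva
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
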