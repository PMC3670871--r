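Package: sizeStability
Title: Sample-Size Sensitivity of Differential Expression, Gene Rank
    Stability and Classifier Accuracy
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies how the sample size of a two-class expression study
    affects its conclusions. Given a log-scale expression matrix and a binary
    phenotype (the canonical example is sex in human skeletal muscle
    microarrays), the package draws balanced class-stratified subsamples over
    a grid of sizes, profiles the stability of per-gene t-test p-values and
    rank order across repeated subsamples, calibrates subsample-to-subsample
    subject overlap with the Jaccard score, and traces learning curves of
    L1-penalized logistic (lasso) sex classifiers under internal
    cross-validation or external-cohort evaluation. A synthetic-data
    generator with planted effects makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    glmnet,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
biocViews: GeneExpression, DifferentialExpression, Classification,
    Microarray, Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
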