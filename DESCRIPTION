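Package: tmesubtyper
Title: Tumor Microenvironment Subtyping from Bulk and Single-Cell Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers and classifies tumor-microenvironment (TME) subtypes
    from transcriptomic data. Estimates 23 TME cell-infiltration features per
    sample (22 cell-type fractions by nu-support-vector-regression
    deconvolution against a signature matrix, plus a fibroblast marker-mean
    score), discovers three subtypes -- Immune Exclusive (IE), Immune
    Suppressive (IS) and Immune Activated (IA) -- by resampling consensus
    clustering with PAC-based model selection, derives a subtype-specific
    feature-gene panel (pairwise Wilcoxon differential expression, removal of
    shared genes, random-forest importance reduction), trains a six-algorithm
    probability-averaging ensemble classifier (SVM, random forest, neural
    network, gradient boosting, decision tree, k-nearest neighbors), and
    applies it to new bulk cohorts and to single-cell data via pseudobulk
    aggregation. A synthetic-cohort generator with planted subtype structure
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    e1071,
    randomForest,
    xgboost,
    nnet,
    rpart,
    caret,
    pracma,
    jsonlite,
    withr,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
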