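Package: traumaViper
Title: Plasma Protein Panel Analysis and Survival Scoring for Trauma Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for multiplex plasma-protein (cytokine and
    chemokine) panels measured in trauma patients and healthy controls.
    Provides limit-of-detection (LOD) aware preprocessing of concentration
    matrices, left-censored Gaussian (Tobit) regression with percent-change
    reporting and directional false-discovery-rate control, below-LOD
    prevalence comparison, all-pairs analyte-ratio screening, random-forest
    permutation importance with per-iteration 0-100 normalization, ROC/AUC
    evaluation with DeLong confidence intervals and Wilson score intervals,
    and derivation plus cross-validated evaluation of a five-analyte
    logistic survival score (VIPER). Includes a synthetic cohort generator
    that emulates the statistical structure of a 59-analyte trauma panel so
    the full pipeline is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Rcpp,
    glmnet,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
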