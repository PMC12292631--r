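Package: kdscreen
Title: Imbalance-Aware Screening Pipelines for Rare Pediatric Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building rare-event clinical screening models on
    severely imbalanced tabular cohorts, motivated by Kawasaki disease
    detection from routine blood and urine panels. Implements
    clustering-based undersampling (k-means++ partitioning with rule-based
    discard of pure-negative and extremely imbalanced clusters), synthetic
    minority augmentation with pluggable generator backends (kernel density
    estimation and a Gaussian copula) sized to a target class ratio, a
    fidelity audit suite (maximum mean discrepancy, pairwise correlation
    difference, entropy and information gain), a stacking ensemble of
    boosting base learners with out-of-fold meta-features and a logistic
    meta-classifier, and a fixed-recall evaluation harness with threshold
    calibration and recall sweeps. A synthetic dual-institution cohort
    generator provides realistic study conditions for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    rpart,
    glmnet,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
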