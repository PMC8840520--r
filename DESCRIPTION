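Package: imbfuse
Title: Two-Stage Sampling-Based Classification with Decision Fusion for
    Imbalanced Conformational Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting drug-binding versus non-binding protein
    conformations from tables of numeric molecular descriptors under severe
    class imbalance. Provides from-scratch implementations of logistic
    regression (cross-entropy cost with L2 regularization), Gaussian naive
    Bayes, and K-nearest neighbors; SMOTE synthetic minority oversampling and
    random majority undersampling, including the class-inversion rebalancing
    that builds a minority-biased training set of unchanged size; a two-stage
    pipeline that fuses a majority-oriented first stage with a minority-
    oriented second stage via a reconciliation ledger (new/reconfirmed true
    positives and true negatives) and the associated fused accuracy metrics;
    confusion-matrix, sensitivity/specificity, ROC/AUC and F1 evaluation; a
    seeded generator of imbalanced Gaussian descriptor tables for fully
    synthetic end-to-end runs; and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
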