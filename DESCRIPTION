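Package: dentshap
Title: Explainable Machine Learning for Dental Workforce Distribution in
    Underserved Areas
Version: 0.1.0
Authors@R:
    person("Workforce", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying which dentists
    practice in underserved settings (federally qualified health centers,
    dental shortage areas, rural dental shortage areas). Provides a seeded
    synthetic cohort generator with planted nonlinear effects, leakage-free
    preprocessing (missingness and collinearity filters, median imputation,
    one-hot encoding, z-scoring), a calibrated soft-voting classifier
    (ridge logistic regression plus gradient-boosted trees with isotonic
    calibration) evaluated under Monte Carlo cross-validation with
    imbalance-aware metrics and MCC-optimal thresholding, AUC-based SAGE
    global feature importance with inclusion curves, linear / tree /
    marginal SHAP local attribution with an exact enumeration oracle, a
    supervised clustering tree over SHAP values gated by silhouette score,
    and plot-ready reporting with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
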