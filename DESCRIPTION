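Package: hfsurv
Title: Hybrid Majority-Vote Feature Selection for High-Dimensional Survival Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Feature selection for right-censored, high-dimensional survival
    data by majority vote over four base selectors: LASSO-penalized Cox
    regression, SCAD-penalized Cox regression, component-wise likelihood-based
    boosting for the Cox model, and random survival forest variable selection
    (minimal depth or variable hunting). Features kept by at least three of the
    four selectors form the final set. Includes Cox proportional-hazards and
    random survival forest predictors, censoring-aware evaluation metrics
    (IPCW Brier score and its time integral, concordance index over comparable
    pairs, integrated absolute and squared error against the Kaplan-Meier
    reference), a Weibull proportional-hazards simulator with calibrated
    independent censoring, and a benchmarking harness over the selector by
    predictor grid.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
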