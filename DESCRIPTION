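Package: fairadjust
Title: Fairness-Constrained and Penalized Regression for Health Plan Risk Adjustment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Group-fairness metrics and fair least-squares estimators for
    continuous spending outcomes in health plan risk adjustment. Implements six
    estimators (ordinary least squares plus five fairness-aware variants that
    build group constraints or penalties into the least-squares objective),
    a suite of group residual-error fairness measures (net compensation,
    predictive ratios, mean residual difference, fair covariance) alongside
    global R-squared, a stratified cross-validated evaluation harness for
    fit-versus-fairness frontiers, and synthetic-data generators emulating
    claims-like spending populations and misspecification simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    quadprog,
    readr,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
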