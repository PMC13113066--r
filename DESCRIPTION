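Package: boarscan
Title: Scanning-Factor Analysis for Ultrasound-Based Boar Semen Quality Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying how scanning factors
    (image region, probe angle, augmentation strategy, classifier capacity)
    affect image-based prediction of boar semen quality. Generates synthetic
    longitudinal semen-collection records and B-mode-like testis images with a
    controllable, brightness-carried class signal; applies the two-step
    rule-based boar quality labeling; runs subject-level (By-ID) 5-fold
    cross-validation with a pluggable image classifier and decision-level
    probability aggregation at a fixed threshold; and evaluates factor effects
    over the 2x2x2x2 configuration grid with main-effects and two-way
    interaction linear models (ANOVA F-tests, OLS coefficients,
    Durbin-Watson and condition-number diagnostics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    glmnet,
    png,
    tibble,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    lmtest
LinkingTo: Rcpp
Config/testthat/edition: 3
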