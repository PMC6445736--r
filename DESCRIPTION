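Package: varjm
Title: Location-Scale Mixed Models and Joint Models for Biomarker
    Variability and Time-to-Event Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the association between the within-subject
    (visit-to-visit) variability of a longitudinal biomarker, such as
    systolic blood pressure, and a time-to-event outcome.  Provides naive
    per-subject estimators of usual level and variability, Bayesian
    location-scale mixed models with subject-specific log-normal residual
    standard deviations, a two-stage Cox procedure that plugs posterior
    means into a proportional-hazards regression, and a
    shared-random-effects joint model with a piecewise-constant baseline
    hazard.  Includes a Weibull proportional-hazards simulator and a
    replicated simulation harness quantifying regression-dilution and
    informative-truncation biases (bias, RMSE and coverage of log hazard
    ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    survival,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
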