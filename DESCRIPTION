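Package: bdrule
Title: Benefit-Stress Rule Calibration for Mutualistic Population Dynamics
Version: 1.0.0
Authors@R:
    person("Ada", "Whitfield", email = "ada.whitfield@example.org",
           role = c("aut", "cre"))
Description: Tools for interpreting and predicting the outcomes of mutualistic
    systems with the coexistence rule "effective benefit exceeds stress"
    (B > delta). Provides a family of 52 logistic-based mutualism ordinary
    differential equation models with outcome classification, stress
    measurement and critical-stress computation; a machine-learning
    calibration procedure that trains soft-margin support vector machines
    with delta-separable kernels on qualitative coexistence/collapse
    observations and inverts the decision boundary into an empirical benefit
    surface B(v) over experimentally controllable context variables;
    predictors for qualitative and quantitative outcomes based on the ratio
    B(v)/delta; and seeded synthetic scenario generators (complex pair,
    N-mutualist, oscillatory forcing, bystander community) for end-to-end
    validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
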