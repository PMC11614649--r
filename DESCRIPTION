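Package: quetipk
Title: Population Pharmacokinetics and Initial-Dose Optimization of Quetiapine
Version: 0.1.0
Authors@R: person("PPK", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for population-pharmacokinetic analysis of quetiapine
    therapeutic drug monitoring data in schizophrenic patients. Implements a
    one-compartment first-order-absorption structural model, nonlinear
    mixed-effects estimation by first-order conditional estimation with
    interaction (FOCE-I), allometric and drug-drug-interaction covariate
    modelling with stepwise selection, nonparametric bootstrap validation,
    goodness-of-fit diagnostics including a visual predictive check, and Monte
    Carlo simulation of virtual patients to derive initial-dose recommendations
    against a 100-500 ng/mL therapeutic window. A synthetic-cohort generator
    reproduces the sparse-sampling structure of hospital TDM data so the whole
    pipeline is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
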