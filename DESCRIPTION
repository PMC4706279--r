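Package: ddilong
Title: Simulation and Analysis of Drug-Drug Interaction Trials for
    Long Half-Life Drugs
Version: 0.1.0
Authors@R: person("ddilong", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools to design, simulate and analyse pharmacokinetic
    drug-drug interaction (DDI) trials for a victim drug with a very long
    terminal half-life and a measured metabolite. Provides a linear
    parent-metabolite compartmental model (transit-chain absorption, three
    parent and two metabolite disposition compartments) solved exactly by
    matrix exponentials with analytic AUCs; a calibrated long-half-life
    example drug; generators for sequential and parallel single-dose DDI
    trial designs with lognormal between-subject variability and correlated
    interaction-effect random effects; non-compartmental analysis (trapezoid
    AUC, adjusted-R-squared terminal-slope selection, geometric mean ratios);
    a Laplace-approximation nonlinear mixed-effects estimator of all model
    parameters including separate interaction effects on parent and
    metabolite clearance; posterior predictive checks; and a study engine
    that quantifies bias and precision of NCA-based versus model-based DDI
    predictions across designs and variability scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
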