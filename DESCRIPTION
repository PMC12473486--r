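Package: bepbbm
Title: Biorelevant Transfer-Dissolution Modeling and Physiologically Based
    Biopharmaceutics Prediction of Oral Drug Absorption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic modeling of a two-chamber gastric-to-intestinal
    transfer dissolution/permeation apparatus (growing fluid volume under
    zero-order biorelevant-medium infusion, pH- and micelle-dependent
    permeation through a partially wetted filter, z-factor dissolution and
    supersaturation-driven precipitation of weak bases), nonlinear
    least-squares estimation of formulation-specific dissolution and
    precipitation rate constants from donor/receiver time courses, and a
    human physiologically based biopharmaceutics model (PBBM) that carries
    the fitted constants into predicted plasma concentration profiles.
    Includes non-compartmental analysis, prediction-error scoring against
    observed pharmacokinetic parameters, and a synthetic-data generator for
    apparatus and dialysis-cell experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    lhs,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    Matrix,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
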