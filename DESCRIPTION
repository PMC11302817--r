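Package: arcqa
Title: Delivery-Error Simulation, Gamma Analysis and CNN Error
    Classification for Cylindrical-Array Patient-Specific QA
Version: 0.1.0
Authors@R:
    person("arcqa", "developers", email = "arcqa@example.org",
           role = c("aut", "cre"))
Description: Tools for patient-specific quality assurance of IMRT and VMAT
    radiotherapy plans measured on a cylindrical diode array.  Simulates
    paired calculated/measured detector dose maps carrying a single
    delivery error (gantry, collimator or couch rotation of 1 degree, or a
    2 percent monitor-unit scaling), computes the per-diode gamma index
    and gamma pass rate under clinical criteria on the cylinder surface,
    prepares augmented five-fold cross-validation datasets, trains a small
    dual-channel convolutional network that classifies the error type from
    the map pair, and compares the network against gamma-pass-rate
    thresholding with ROC/AUC, confusion matrices and binary-collapse
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
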