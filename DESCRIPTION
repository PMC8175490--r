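Package: packinetics
Title: Kinetic Modelling of Batch (R)-Phenylacetylcarbinol Biotransformation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and parameter estimation for the batch enzymatic
    carboligation of benzaldehyde and pyruvate to (R)-phenylacetylcarbinol
    (PAC) by pyruvate decarboxylase in phosphate buffer. Implements a
    six-state kinetic model (PAC, pyruvate, benzaldehyde, acetaldehyde,
    acetoin, relative enzyme activity) with Hill-type benzaldehyde binding,
    Michaelis-Menten pyruvate saturation, and first-order enzyme
    deactivation offset by a zeroth-order phosphate-buffer activation term
    with an initial lag. Provides explicit-Euler simulation, a residual
    sum-of-squares grid-search fitting procedure with profile refinement
    of weakly identified constants, fit statistics (RSS, MSE, R-squared),
    batch summary metrics (maximum PAC, formation rate, molar yields), a
    synthetic-data generator reproducing the study design, and tidy
    plotting/reporting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
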