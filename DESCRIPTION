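Package: microdcm
Title: Canonical-Microcircuit Dynamic Causal Modelling of Auditory Mismatch Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and variational Bayesian inversion of canonical
    microcircuit (CMC) neural-mass models of six-source auditory mismatch
    evoked responses. Provides a fast compiled integrator for the coupled
    cortical-column dynamics, a 21-model network architecture space with
    hierarchical family partitions, variational-Laplace model inversion with
    free-energy model evidence, fixed- and random-effects Bayesian model
    selection with exceedance probabilities, conventional mismatch-negativity
    features and group statistics, and permutation leave-one-out support
    vector machine classification from model parameters (generative
    embedding). A synthetic-cohort module generates oddball paradigms and
    ground-truth patient/control cohorts with planted laminar effects so the
    whole pipeline is testable without recorded data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
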