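Package: caliberflow
Title: Fluctuation-Response Analysis and Gradient-Based Design of Markov Jump Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Exact steady-state response theory for ergodic, reversible Markov
    jump processes on networks. Builds the spanning-tree/fundamental-cycle
    observable basis (edge traffic, node dwell, cycle net flux), the conjugate
    caliber forces, and the sparse Jacobian linking log transition rates to
    forces.  The inverse Jacobian delivers exact response gradients of every
    steady-state rate observable to every rate constant, asymptotic covariances
    of counting observables by projection onto independent per-transition noise
    sources, the randomness parameter (Fano factor) of a net flux and its exact
    per-transition sensitivity decomposition, and analytic gradients of
    variances via the algebraic closure of the inverse matrix.  Ships audits of
    the universal node/edge/cycle response symmetries and the kinetic bound
    hierarchy on one-way flux responses, together with independent verification
    oracles: exact stochastic (Gillespie) simulation with counting statistics,
    tilted-generator spectral cumulants, and finite-difference responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
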