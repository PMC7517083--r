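Package: stochpop
Title: Spectral and Sampling Solvers for the Stochastic Logistic Population Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for uncertainty quantification in the stochastic Verhulst
    (logistic) population model driven by multiplicative white noise and an
    uncertain growth rate. Implements a second-order Wiener-Hermite expansion
    (WHE) kernel solver via an explicit finite-difference scheme, a coupled
    generalized polynomial chaos (gPC) plus WHE solver for a uniformly
    distributed random growth rate, decomposition of the solution variance into
    Gaussian/non-Gaussian and noise/parameter/mixed components with
    variance-based sensitivity indices, and sampling-based references
    (Euler-Maruyama, the exact pathwise solution, and nested parameter-noise
    Monte Carlo) for validation. Closed-form deterministic (logistic, Richards)
    solutions and stationary gamma-distribution moments are included as
    analytic oracles, together with experiment presets, CSV writers and a thin
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    pracma,
    stats,
    utils
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
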