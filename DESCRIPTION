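Package: neuralfield
Title: Stochastic Neural Field Models: Master-Equation Simulation and
    Mean-Field Limit Verification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and numerical verification toolkit for stochastic
    neural field models. Implements exact (thinning-based) simulation of
    master-equation neuron population models on partitioned spatial
    domains, deterministic solvers for the Wilson-Cowan equation and its
    bounded-state-space variant, spectral negative-order Sobolev norms,
    martingale extraction with the limiting diffusion covariance of the
    central limit theorem, Langevin and linear-noise stochastic field
    approximations, and moment-equation closures. Includes scenario
    presets and experiment drivers that exercise the law of large numbers
    and the martingale central limit theorem of the mean-field limit at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
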