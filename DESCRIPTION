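Package: csdscale
Title: Scaling Laws of Critical Slowing Down at the Transition to Neuronal Spiking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of critical slowing down near the
    bifurcation that takes a neuron from quiescence to repetitive spiking.
    Provides stochastic saddle-node and subcritical Hopf normal-form
    simulators with a slowly drifting control parameter and impulsive
    perturbations, an emulator of a patch-clamp step-current stimulation
    protocol, per-perturbation estimation of recovery rate, variance and
    autocorrelation, power-law fitting of these markers against the distance
    to the bifurcation with a minimal-distance sweep, classification of the
    underlying bifurcation from the fitted exponents, and prediction of the
    critical (spiking) voltage from truncated recovery-rate series using a
    fixed scaling exponent.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
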