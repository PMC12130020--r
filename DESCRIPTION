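Package: caadex
Title: Two-Compartment Adaptive Exponential Neurons with Dendritic Calcium Dynamics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and fitting of two-compartment (and general
    tree-structured multi-compartment) adaptive exponential
    integrate-and-fire neurons carrying a dendritic calcium hot zone, the
    configuration known as Ca-AdEx.  Provides a linearized Crank-Nicolson
    time stepper solved on the compartment tree by the Hines algorithm with
    exponential-propagator channel gating, conductance-based AMPA/GABA/NMDA
    receptors, back-propagating action-potential coupling, the pulse
    (BAC-firing) and prolonged-DC stimulation protocols, the piecewise-planar
    ThetaPlanes approximation of the firing-rate transfer function
    nu(I_s, I_d), a fitness-function suite with a genetic-algorithm outer
    loop for parameter fitting, brain-state modulation presets
    (apical-amplification, -isolation, -drive) and a balanced Brunel-like
    network benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
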