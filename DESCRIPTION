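Package: gridplace
Title: Coupled Place-Cell and Grid-Cell Attractor Network Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a one-dimensional rate model of the coupled
    hippocampal-entorhinal circuit in which several spatial maps are embedded
    in the recurrent connectivity of a place-cell network, and three grid-cell
    modules are modeled as double-ring attractors.  Bidirectional synapses
    between the two sub-networks are set from the overlap of idealized tuning
    curves across all maps.  The package builds the connectivity, integrates
    the stochastic rate dynamics with velocity and perturbation inputs,
    decodes population states into maps and positions with template matching,
    and reproduces the standard experiment suite: persistence of joint bump
    states, path integration and hippocampal lag, noise-driven drift and
    module coordination, grid-field rate variability, and artificial
    remapping of place fields under grid-cell depolarization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
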