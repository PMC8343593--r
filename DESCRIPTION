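Package: gyrogenesis
Title: Growth-Driven Cortical Folding Simulation and 3-Hinge Gyral
    Pattern Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Finite-growth biomechanical simulation of cortical folding on
    a bilayer slab (neo-Hookean cortex and core with multiplicative growth
    decomposition, quasi-static nonlinear finite elements) together with a
    surface-based gyral-net extraction pipeline that detects 3-hinge gyral
    patterns (junctions where three gyral crest lines meet).  Includes
    analytic surface fixtures with known hinge structure, perturbation
    ensembles, fiber-bundle templates with gradient axial growth, and
    thickness/area sweeps with count-prediction fits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
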