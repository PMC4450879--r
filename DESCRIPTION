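Package: tendonpve
Title: Fibre-Reinforced Poroviscoelastic Modelling of Tendon Under Tensile Loading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Biphasic (poroviscoelastic) fibre-reinforced continuum model of tendon
    tissue with an axisymmetric displacement/pore-pressure finite-element solver.
    The solid skeleton combines tension-only collagen fibres, modelled as a modified
    standard linear solid with exponential springs integrated by a backward-Euler
    quadratic update, and a compressible neo-Hookean non-fibrillar matrix; the fluid
    phase follows Darcy flow with void-ratio-dependent permeability. Includes virtual
    mechanical-test protocols (cyclic tension, strain stiffening, creep, stress
    relaxation, horizontal-fibre control), inverse parameter identification against
    force-displacement records by Nelder-Mead in transformed coordinates, and a
    synthetic-cohort generator that emulates cyclic 1-20 N tensile testing of rat
    Achilles tendons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
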