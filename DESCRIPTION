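Package: memflex
Title: Membrane Bending Modulus Estimation from Coarse-Grained Bilayer Trajectories
Version: 0.1.0
Authors@R:
    person("memflex", "developers", email = "memflex@example.org", role = c("aut", "cre"))
Description: Estimates the bending modulus of lipid bilayer membranes from
    coarse-grained trajectory ensembles using three independent routes: the
    Helfrich undulation spectrum (q^-4 fit with optional tension term), the
    Bedeaux-Weeks density correlation function (coupled-undulation q-dependent
    surface tension), and real-space splay fluctuations with Boltzmann
    inversion. Includes membrane geometry observables (bilayer thickness, area
    per lipid, leaflet density profiles, lateral diffusion), a GRO reader and a
    plain-text trajectory dialect, and a synthetic equilibrium-ensemble
    generator with known ground-truth mechanics so every estimator is testable
    by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
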