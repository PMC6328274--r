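Package: mcdpos
Title: Brownian-Ratchet Simulation of McdA/McdB-Mediated Carboxysome Positioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulator and analysis toolkit for carboxysome
    positioning on the bacterial nucleoid by the McdA/McdB system. Implements
    a Brownian-ratchet model in which disk-shaped cargos carrying McdB form
    transient elastic tethers to nucleoid-bound McdA, stimulate its release
    into a refractory cytosolic pool, and thereby self-generate the McdA
    depletion zones that drive directed segregation. Includes a kinetic
    Monte Carlo engine (tau-leaped surface chemistry coupled to overdamped
    Langevin cargo dynamics on 2D rod-shaped or circular nucleoid domains),
    ensemble execution, arrangement classification (linear, staggered,
    clustered), motility-regime detection, depletion-zone metrics, and
    synthetic-data generators with known ground truth for validating every
    analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
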