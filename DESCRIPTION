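Package: tristem
Title: Tri-Stable Switch Simulation of Stem-Cell Homeostasis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Stochastic simulation of stem-cell population homeostasis driven
    by an intracellular tri-stable gene-regulatory switch. Provides two-,
    four-, and six-element mutual-inhibition/self-activation Hill circuits,
    deterministic phase-plane analysis (nullclines, fixed points, linear
    stability, attractor basins), an exact Gillespie engine for populations of
    dividing cells with binomial partitioning of fate determinants at
    division, attractor-basin fate classification of daughter cells, and an
    eleven-phase mutation-accumulation protocol with survival, stem-cell-birth
    rate, swarm, and population-size metrics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
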