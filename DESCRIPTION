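Package: thallus
Title: Lattice-Free Binary-Tree Simulation and Branching-Angle Analysis
    of Fungal Thallus Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Two-dimensional, lattice-free stochastic simulation of the
    vegetative growth of a filamentous fungus (modelled on Podospora
    anserina): full-binary-tree apical branching with Gamma-distributed
    branch lengths and Gaussian branching angles, power-law lateral
    branching, a measurement-artifact observer (resolution blur, geometric
    branch crossings, apex-branch merges, ghost vertices), base-2
    growth-curve calibration, surface-occupancy optimization of the apical
    branching angles, and two branching-angle measurement pipelines: a
    direct circle method on vector networks and a raster
    skeleton/buffer method with a constrained three-Gaussian fit of the
    angular spectrum.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    minpack.lm,
    yaml,
    png,
    jsonlite,
    EBImage
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
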