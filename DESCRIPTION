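Package: hybridcell
Title: Hybrid Discrete-Cell and Continuum-Oxygen Simulation of Multicellular Growth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Center-based simulation of large multicellular systems coupled to a
    continuum extracellular microenvironment. Cells are spheres with a stochastic
    five-phase cycle (premitotic, postmitotic, quiescent, apoptotic, two-stage
    necrotic), component-volume relaxation dynamics, and short-range
    adhesion/repulsion mechanics resolved in linear time through Morton-code
    voxel sorting. Oxygen transport is solved on the shared Cartesian grid by a
    first-order operator-split finite-volume scheme: locally one-dimensional
    (LOD) diffusion-decay sweeps via the Thomas algorithm, then an implicit
    supply/uptake update coupled to the discrete cells. Ships hanging-drop
    spheroid and ductal carcinoma in situ scenarios, scalar growth metrics, and
    CSV/VTK snapshot output.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
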