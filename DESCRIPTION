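Package: cellagg
Title: Agent-Based and Smoluchowski Models of Cell Aggregation on Soft Substrates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and analyzes the spontaneous aggregation of weakly
    adherent cells on soft hydrogel substrates. Provides an off-lattice 2D
    agent-based model of disk-shaped cells in a periodic box (random motion,
    contact adhesion, partial superimposition, aggregate compaction, flux
    bias, proliferation), an image-style measurement stage yielding
    aggregate counts and mean projected areas over time, the spaceless
    Smoluchowski coagulation model with constant and monomer-only kernels
    including kernel fitting and model selection, and a grid-search
    calibration workflow for recovering cell motility and proliferation
    parameters from reference curves.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    png,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
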