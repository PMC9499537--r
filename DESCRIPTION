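Package: erkwave
Title: Apoptosis-Triggered ERK Wave Analysis in Organoid Monolayer Time-Lapse Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies apoptosis-triggered ERK trigger waves and crypt-like
    node patterning in time-lapse fluorescence imaging of intestinal organoid
    monolayers. Provides nuclear segmentation from an H2B channel with
    annulus-based kinase translocation reporter (KTR) measurement, optimal
    frame-to-frame cell tracking, apoptosis-referenced movement statistics
    (dNuc/Mov/deltaMov), distance-ordered kymographs, wave speed/extent/
    duration estimation, DBSCAN clustering of ERK-active cells with cumulative
    activity heat maps, node detection and spacing statistics, per-cell
    intensity quantification, and particle image velocimetry of collective
    flow. Includes an agent-based synthetic-monolayer simulator that renders
    calibrated H2B/KTR/caspase image stacks with full ground truth so every
    estimator can be validated in closed loop.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
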