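Package: holocell
Title: Off-Axis Holographic Phase Reconstruction and Cell-State Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: End-to-end quantitative phase imaging (QPI) pipeline for
    label-free cell-state cytometry: windowed least-squares demodulation of
    off-axis interferograms, Goldstein branch-cut phase unwrapping,
    single-cell segmentation, a ten-parameter optical feature vector
    (average phase, phase volume / dry mass, projected and phase-surface
    areas, sphericity, phase-distribution moments, eccentricity), recovery
    of 3D morphology (height, volume, membrane surface) under the
    constant-refractive-index assumption, and machine-learning
    classification of cell line (HeLa/A549/3T3) and cell state
    (live/apoptotic/necrotic), including time-resolved fractions of dying
    cells. A parametric cell-phantom and hologram simulator provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    graphics,
    grDevices,
    jsonlite,
    png,
    randomForest,
    Rcpp,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
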