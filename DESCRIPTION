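Package: mammoplan
Title: Silhouette-Based Torso Reconstruction and Breast Implant Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline toolkit for quantitative breast-augmentation
    consultation planning. Reconstructs a patient-specific 3D torso surface
    from three landmarked 2D views (frontal and two laterals) plus two
    anthropometric measurements, simulates implant placement (subglandular,
    submuscular or dual plane) with a voxelized relaxed-constraint elastic
    tissue model, and validates reconstructed or simulated surfaces against
    reference scans by rigid registration, breast cropping and directed
    surface-to-surface distance with box-plot summaries. Includes a
    parametric torso phantom generator for end-to-end synthetic evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    png,
    igraph,
    tibble,
    dplyr,
    ggplot2,
    generics,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
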