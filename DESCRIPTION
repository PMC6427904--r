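Package: gliovox
Title: Supervised Voxel-Wise Brain Tumor Segmentation from Multi-Modal MRI
Version: 0.1.0
Authors@R: person("gliovox", "maintainers", email = "gliovox@example.org", role = c("aut", "cre"))
Description: Voxel classification pipeline for glioma segmentation in
    co-registered multi-modal MR volumes (Flair, T1, T1c, T2). Implements a
    62-dimensional feature bank of 2D/3D gradient-magnitude neighborhood
    statistics and circular context-sensitive ray features, minimal-redundancy
    maximal-relevance (mRMR) feature ranking with a dimension-sweep
    model-selection harness, class-balanced random-forest training inside a
    detected region of interest, subject-level cross-validation, and
    region-composite evaluation (complete, core, enhancing tumor) with Dice,
    PPV, sensitivity and specificity. Ships a nested-ellipsoid multi-modal
    phantom generator so the full pipeline is exercisable without external
    data, and minimal NIfTI-1 and MetaImage volume I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
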