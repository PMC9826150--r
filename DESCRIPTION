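Package: poremorph
Title: Cortical Pore Segmentation and Morphometry for Histological Bone Sections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A scriptable pipeline for quantifying cortical porosity on
    brightfield images of transverse bone cross-sections. Isolates the cortex
    by tolerance-based wand selection and border derivation, enhances images
    with a composable preprocessing sequence, segments pore spaces with global
    and Phansalkar local thresholds plus distance-map morphology, classifies
    each pore as cortical or trabecularized by an endosteal Euclidean
    distance-map rule, partitions pores into anatomical regions, and reports
    per-pore and per-region morphometry including cross-sectional second
    moments of area. Includes readers and writers for TIFF images and ImageJ
    ROI archives, and a deterministic synthetic cross-section generator with
    planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tools,
    Rcpp,
    tibble,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
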