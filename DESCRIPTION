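Package: pdl1tps
Title: Automated PD-L1 Tumor Proportion Scoring for DAB-Stained Histology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Three-stage automated scoring of PD-L1 expression in
    DAB-stained non-small cell lung cancer histology images: tumor patch
    classification, positive/negative tumor-region segmentation (including
    a DeepLabV3+ variant whose convolutions are replaced by self-organized
    operational Self-ONN layers), and star-convex-polygon nucleus detection
    on the deconvolved hematoxylin channel. Detected nuclei are assigned to
    stained regions and aggregated into a per-slide tumor proportion score
    (TPS) with the three clinical expression levels (<1%, 1-49%, >=50%).
    Includes a synthetic H-DAB slide generator with exact ground truth
    (region masks, nucleus centroids, per-slide TPS) so every stage is
    testable end to end, a compact CPU conv-net engine with hand-derived
    backpropagation, slide-level cross-validation utilities, and the full
    set of classification, segmentation and slide-agreement metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
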