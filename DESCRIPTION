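Package: cecounter
Title: Semi-Supervised U-Net Counting of Cultured Corneal Endothelial Cells
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects cell centers in phase-contrast micrographs of cultured
    human corneal endothelial cell (HCEC) monolayers with a small U-Net pixel
    classifier, and converts detections into cell densities (cells per square
    millimetre) and total-cell-number estimates for culture vessels. Implements
    a two-stage semi-supervised workflow: an initial model trained on a small
    manually annotated pool pseudo-labels a larger unlabeled pool; corrected
    pseudo-labels are merged and used to train the final cell-count model.
    Includes a seeded synthetic phase-contrast image generator (Voronoi cell
    mosaics with known center coordinates) so the full pipeline is testable
    without microscope data, plus point-matching precision/recall/F evaluation
    with bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
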