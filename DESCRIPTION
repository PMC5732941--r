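Package: cells3d
Title: Automatic Detection and Counting of Fluorescently Labeled Cells in 3D
    Microscopy Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection and counting of fluorescently labeled cells (nuclei)
    in 3D fluorescence microscopy volumes such as confocal or light-sheet
    stacks of whole-mount tissue and thick sections. The pipeline combines
    histogram matching across samples, subtraction of a co-registered
    autofluorescence channel, Gaussian difference-of-Gaussians band-pass
    filtering in the frequency domain, intensity thresholding, 3D watershed
    splitting of touching cells, and a per-segment bootstrap significance
    test based on log-linear 3D Gaussian fits of the unfiltered intensities.
    Includes precision/recall/F-score evaluation against ground-truth
    centroid tables, a decibel signal-to-noise measure, and a synthetic
    volume generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite,
    optparse
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr
Config/testthat/edition: 3
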