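Package: inrfqa
Title: Full-Reference Image and Video Quality Metrics Based on a
    Nonlinear Receptive-Field Transform
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements a full-reference image quality metric built on an
    intrinsically nonlinear receptive-field (INRF) image transform: each
    image is mapped to a "perceptual" domain by a neural-summation model
    combining a linear Gaussian term with a nonlinear term whose sigmoid
    operating point shifts with the local mean, and quality is the mean
    squared difference of the transformed images.  A video extension
    applies the metric frame-wise with resolution-dependent kernel scaling
    and frame-rate alignment by reference-frame dropping or distorted-frame
    duplication.  Also provides the standard correlation evaluation
    protocol (Spearman rank correlation; Pearson correlation after a
    four-parameter logistic mapping), a grid-search parameter optimizer,
    synthetic image/video/distortion generators for dependency-free
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
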