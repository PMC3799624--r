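Package: fdsvel
Title: Direct Boundary Modeling of Fluorescence-Detected Sedimentation
    Velocity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of sedimentation velocity data recorded with the
    confocal fluorescence detection system (FDS) for the analytical
    ultracentrifuge. Solves the Lamm equation for ideal species in a
    sector-shaped cell with a conservative finite-volume scheme, augments
    the sedimentation model with detector-specific signal transforms
    (radial magnification gradients, temporal intensity drift,
    beam-shadowing at the cell bottom, Gaussian radial convolution, and an
    optional power-law signal non-linearity), and fits c(s) sedimentation
    coefficient distributions by regularized non-negative least squares
    with algebraic decomposition of time-invariant and radial-invariant
    systematic noise. Includes reading and writing of plain-text radial
    scan files, a synthetic-data generator with known ground truth,
    serial (batch) fitting, gain-linearity analysis, signal-increment
    surfaces, and detection-beam angle estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
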