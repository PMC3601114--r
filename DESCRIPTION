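Package: synergyflow
Title: Motor Module Analysis of Perturbed and Unperturbed Cutting Manoeuvres
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of the modular control of fast changes in
    direction while running: surface EMG envelope construction (band-pass,
    rectification, 10 Hz low-pass, 200-point cycle normalization), extraction
    of motor modules (muscle synergies) and activation signals by
    non-negative matrix factorization with multiplicative updates,
    variance-accounted-for (VAF) dimensionality selection, normalized
    scalar-product similarity and fixed-factor cross-reconstruction between
    conditions, knee co-contraction ratio and index over stance epochs, and
    centre-of-mass power based stance segmentation and external work. Includes
    a synthetic-data generator with planted ground truth for parameter
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    pracma,
    signal,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
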