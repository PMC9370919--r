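Package: qrefa
Title: Quick-Response Eigenface Analysis for Motor-Imagery EEG Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Converts epoched multi-channel motor-imagery EEG trials into
    two-dimensional neuro images, extracts an eigenface basis by the snapshot
    covariance method, restructures the leading eigenvectors into standardized
    small "QR" images, synthesizes per-trial QR train/test images from the
    projection coefficients, augments the limited training images with
    multiplicative Gaussian brightness noise, classifies them with a minimal
    convolutional neural network, and reports pooled success rates with
    Student-t confidence intervals over repeated simulations. Includes a
    synthetic EEG cohort generator with class-specific spatial patterns and
    band-limited oscillations so the whole pipeline is testable without any
    external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    withr,
    png,
    yaml,
    jsonlite,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
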