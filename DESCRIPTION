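Package: neurotrackr
Title: Neuron Tracking and Fluorescence Mask Overlay for Patch-Clamp
    Video Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracks a user-selected region of interest (typically a neuron
    targeted for patch-clamp recording) across transmission microscopy
    frames and overlays a previously acquired fluorescence mask on the
    live image, so the tissue is not re-exposed to excitation light.
    Implements a scale-space box-filter blob detector built on integral
    images, 64-dimensional Haar-wavelet descriptors, Laplacian-sign-gated
    nearest-neighbour matching, seeded RANSAC homography estimation,
    alpha-blended compositing, controlled blur/brightness degradations
    with robustness sweeps, and a seeded generator of microscopy-like
    synthetic images with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
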