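Package: semgimage
Title: Image Encodings and Multi-Stream Convolutional Networks for
    Surface-EMG Gesture Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Converts windowed multi-channel surface-electromyography (sEMG)
    envelope signals into three complementary two-dimensional image encodings
    -- a channel-rearrangement image (Sigimg), per-channel Gramian angular
    difference fields (GADF), and per-channel Markov transition fields (MTF)
    -- and classifies gestures with a multi-stream convolutional neural
    network fused at the fully connected layers.  Includes sliding-window
    segmentation, db4 wavelet denoising and anti-aliased downsampling for raw
    arm-band exports, a Ninapro-style MAT v5 reader and writer, a synthetic
    sEMG envelope generator for offline testing, repetition-wise train/test
    splitting, a pure-R/Rcpp training engine with the Adam optimiser, and
    per-subject accuracy, precision, recall and confusion-matrix reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    ggplot2,
    generics,
    jsonlite,
    readr,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
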