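Package: ecgan
Title: ECG Arrhythmia Beat Classification with GAN Augmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end pipeline for heartbeat-level arrhythmia
    classification on single-lead ECG: discrete-wavelet (db6) soft-threshold
    denoising, Pan-Tompkins QRS detection and 150-sample beat segmentation,
    mapping of MIT-BIH annotation symbols to the five AAMI beat classes,
    generative-adversarial augmentation of minority classes with a 1D
    convolutional GAN, and a residual-convolution + bidirectional-LSTM +
    attention classifier, together with per-class accuracy/sensitivity/
    specificity and one-vs-rest ROC evaluation. Includes a synthetic ECG
    generator (Gaussian wave components plus baseline wander, powerline and
    EMG noise) with known R-peak ground truth so the whole pipeline is
    testable without external data, and a reader/writer for WFDB-format
    records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
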