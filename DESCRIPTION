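Package: intentfuse
Title: Modular Bayesian Sensor Fusion for Multimodal Intent Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for drop-in/drop-out intent classification from multimodal
    wearable sensor networks. Provides a synthetic generator for labelled
    multi-rate surface-electromyography (sEMG) and inertial-measurement-unit
    (IMU) trials, signal conditioning (Butterworth band-pass filtering, MVIC
    normalisation, sliding-window segmentation), standard sEMG time- and
    frequency-domain feature extraction, per-sensor k-nearest-neighbour
    classifiers, confusion-matrix-weighted Bayesian decision fusion that lets
    sensors join or leave the network without retraining, and an evaluation
    harness covering leave-one-out protocols, classification-horizon sweeps,
    sensor-count sweeps and simulated sensor-dropout experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
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
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
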