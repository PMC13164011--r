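Package: graspfusion
Title: Multimodal Tactile Grasp Simulation and Transformer Fusion
    Classification for Frost-Damage Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates multimodal robotic-grasp recordings (6x6 pressure-matrix
    streams at ~20 Hz and piezoelectric vibration streams at ~200 Hz, 10-bit ADC
    counts) of normal and frost-damaged fruit, preprocesses them into fixed-length
    model inputs (grasp segmentation, temporal denoising, Butterworth high-pass
    filtering, resampling to 50 time steps, per-trial normalisation), and trains a
    dual-branch single-block Transformer fusion classifier together with
    single-modality ablations and RNN/CNN/LSTM baselines under a repeated
    stratified-split evaluation protocol. Residual-aware attention rollout yields
    per-sample temporal attribution profiles, peak-attribution times and
    peak-interval histograms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
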