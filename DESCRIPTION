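Package: gaitphase
Title: Interpretable Patch-Token Transformers for Continuous Gait-Phase
    Estimation from Multimodal Wearable Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous gait-phase estimation (0-100% of the gait cycle) from
    synchronized wearable-sensor recordings (IMU, surface EMG and knee stretch
    sensors). Provides the full pipeline: foot-pressure based stride
    segmentation and phase labelling, circular sin/cos phase encoding, sliding
    window datasets, a channel-token patch transformer whose cross-attention
    weights yield per-channel importance scores, attention-guided sensor
    channel selection, CNN/LSTM/GRU baseline families, phase-stratified
    evaluation metrics, and a synthetic multimodal gait-signal generator with
    known ground-truth phase for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
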