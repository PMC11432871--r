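Package: vo2net
Title: Oxygen Uptake Estimation from Wearable Gait and Heart-Rate Data with Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for estimating oxygen uptake (VO2)
    during outdoor walking and running from step-wise gait features and heart
    rate. Provides a synthetic cohort generator with first-order VO2/HR on-off
    kinetics and a randomized multi-speed track protocol; preprocessing
    (Savitzky-Golay and moving-average smoothing, cross-correlation stream
    synchronization, resampling onto step times, sequence windowing); a
    self-contained neural-network engine with recurrent (RNN/LSTM/GRU),
    convolutional, residual, densely connected and depthwise-separable
    (Xception-style) regression heads in a dual-branch architecture with an
    optional participant-attribute branch; and evaluation machinery
    (intra-subject splits, leave-one-subject-out cross-validation, RMSE
    aggregation and ranking, Bland-Altman agreement, Pearson/Spearman
    correlation reports).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
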