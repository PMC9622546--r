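Package: emohyst
Title: Perceptual Hysteresis Analysis for Dynamic Facial Emotion Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Models the morph-stimulus protocol of dynamic facial-emotion
    transition experiments, quantifies perceptual hysteresis from
    button-press reports and static three-way classifications, and analyses
    region-of-interest BOLD time series with first-level GLMs, percent
    signal change, event-related averaging, generalized psychophysiological
    interaction (gPPI) connectivity, and sliding-window partial Spearman
    correlation dynamics. Ships a synthetic-observer and BOLD simulator
    with known ground truth so every analysis stage is testable end to end
    without human data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    MASS,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
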