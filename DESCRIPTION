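Package: caprilung
Title: Abnormal Goat Lung-Sound Recognition with an Axial-Attention
    Windowed Transformer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for classifying goat lung-sound recordings
    into normal, rhonchi, tachypnea and noise categories. Provides WAV and
    label-sidecar input/output with overlapping segmentation, zero-phase
    Butterworth bandpass preprocessing, SMOTE class balancing in feature
    space, gammatone (ERB-scale) time-frequency features, a hierarchical
    windowed-attention classifier with axial time-frequency attention,
    salience-masked adaptive downsampling and a frequency-band-aware
    feed-forward block, stratified (optionally grouped) k-fold training and
    evaluation with respiratory-sound sensitivity/specificity metrics, and a
    class-conditional synthetic lung-sound generator so the whole pipeline
    is testable without animal data. The network forward and backward passes
    run on a small reverse-mode automatic-differentiation engine included in
    the package.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
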