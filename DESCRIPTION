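Package: eegaffect
Title: EEG Emotion Detection with Differential-Entropy Features and a Residual CNN
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An offline-testable pipeline for EEG-based affect detection:
    seeded synthesis of 62-channel EEG with class-dependent band-power
    structure, preprocessing to a 200 Hz / 0-75 Hz contract, band-wise
    differential-entropy features smoothed by a linear dynamic system,
    224 x 224 standardized feature images, a residual convolutional
    network (bottleneck blocks, Adam, categorical cross-entropy) for
    3-class emotion recognition, mapping of class probabilities to a
    1-100 pleasure score, and the detector-versus-questionnaire
    evaluation arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
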