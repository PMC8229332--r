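Package: emocsp
Title: Common Spatial Pattern Analysis of Emotion-Evoked EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for emotion recognition from multichannel
    EEG: segmentation of multi-paradigm trials into one-second epochs,
    max-min amplitude artifact rejection, pre-stimulus baseline correction,
    a zero-phase Butterworth band-pass filter bank (delta through high
    gamma), common-spatial-pattern (CSP) feature extraction with
    log-variance features, one-vs-rest linear discriminant classification
    under trial-wise 10x10 cross-validation, and baseline-relative percent
    band-power-change statistics by scalp region with repeated-measures
    ANOVA. Includes a synthetic multichannel EEG generator with planted
    class-dependent spatial sources, 1/f background noise and injectable
    high-amplitude artifacts, so that every stage of the pipeline can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    signal,
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
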