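Package: anescore
Title: Depth-of-Anesthesia Estimation from Frontal EEG with a Deep
    Residual Shrinkage Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for estimating the depth of anesthesia
    from 4-channel frontal electroencephalography (EEG), expressed as the
    0-100 patient state index (PSI).  Includes a synthetic multi-subject EEG
    generator with depth-dependent band structure and ocular artifacts; a
    preprocessing chain (segmentation, 1-51 Hz linear-phase FIR bandpass,
    and ocular-artifact removal by wavelet decomposition, complete ensemble
    empirical-mode decomposition with adaptive noise, independent component
    analysis and sample-entropy screening); multitaper spectral features
    (band powers, 95% spectral edge frequency, sample entropy); a 1-D deep
    residual shrinkage network regressor with channel-wise learned soft
    thresholds and a 1x1-convolution head; three conventional feature-based
    baselines (SVR, random forest, multilayer perceptron); and an evaluation
    harness with random and subject-grouped five-fold cross-validation,
    macro-averaged state metrics and Spearman rank correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    signal,
    e1071,
    randomForest,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
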