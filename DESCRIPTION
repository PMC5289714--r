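Package: eegresp
Title: EEG-Based Prediction of SSRI Treatment Response in Depression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis workflow for predicting antidepressant (SSRI)
    treatment outcome in major depressive disorder from multichannel
    resting-state EEG. Implements discrete-wavelet (db4), short-time
    Fourier and empirical-mode-decomposition feature extraction on
    19-channel 10-20 recordings, z-score standardization against a
    healthy-control reference, ROC-rank (area-under-curve) feature
    selection with correlation pruning and an mRMR alternative,
    logistic-regression classification under repeated stratified
    10-fold cross-validation, Wilcoxon rank-sum scalp topographies and
    PCA scatter summaries. Includes a synthetic-cohort generator that
    plants group-dependent delta/theta band-power contrasts so that
    every stage of the pipeline can be exercised and validated end to
    end without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
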