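Package: spindler
Title: Automatic Sleep-Spindle Detection from Polysomnographic EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects sleep spindles (sigma-band, 11-16 Hz, fusiform bursts of
    0.5-3 s) in multi-channel polysomnographic EEG. Provides a synthetic EEG
    simulator with ground-truth spindle annotations, EDF reading and writing,
    preprocessing (mean imputation, min-max normalization, 30-s epoch / 10-s
    frame segmentation, stratified train/test splits), four spectral and
    higher-order feature families per frame (Welch/periodogram power spectral
    density band powers, Morlet continuous-wavelet features, a normal
    probability-plot Gaussianity score, and a bispectrum diagonal-slice band
    ratio), a five-classifier bank (KNN, SVM, decision tree, naive Bayes,
    extremely randomized trees) behind one S3 fitting function, and an
    evaluation layer (frame-level confusion matrix and derived metrics, ROC
    and AUC, intraclass correlation of per-recording spindle counts, spindle
    density). A reproducible end-to-end pipeline and a thin command-line
    interface tie the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    rpart,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    class,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
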