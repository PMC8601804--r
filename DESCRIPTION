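Package: cryclass
Title: Acoustic Feature Engineering and a Boosted Support-Vector Committee
    for Neonate Cry Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Classifies neonate cry recordings into hunger, sleep and
    discomfort cries. Implements a seven-step audio preprocessing chain
    (normalization, cry-unit detection, pre-emphasis, framing, Hamming
    windowing, FFT), twelve time- and frequency-domain acoustic features
    (magnitude, average, variance, zero-crossing rate, bandwidth, spectral
    peak/valley, pitch, formants, LPCC, MFCC, delta-MFCC), random-forest
    variable selection, and a grouped-support-vector network: a committee
    of RBF-kernel support-vector classifiers trained on boosting-reweighted
    bootstrap resamples and combined by weighted majority voting. Includes
    stratified k-fold cross-validation with confusion-matrix reporting and
    one-vs-rest ROC, and a seeded source-filter generator of synthetic
    cry-like audio for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
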