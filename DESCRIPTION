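Package: eegdx
Title: EEG Sub-Band Feature Extraction and Neurological Disorder Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Signal-processing and classification toolkit for diagnosing
    neurological disorders (epilepsy, autism spectrum disorder) from EEG
    recordings. Reads single-channel ASCII and multi-channel EDF recordings,
    removes ocular artifacts with reference-channel ICA, band-limits segments
    with a zero-pole-gain elliptic band-pass filter, decomposes each segment
    into delta/theta/alpha/beta/gamma sub-bands with a 4-level Daubechies
    discrete wavelet transform, extracts five sub-band statistics (logarithmic
    band power, standard deviation, variance, kurtosis, Shannon entropy), and
    evaluates LDA, linear one-vs-all SVM, KNN and single-hidden-layer ANN
    classifiers under stratified k-fold cross-validation. Includes a
    class-conditioned synthetic EEG generator so the full pipeline is testable
    without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
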