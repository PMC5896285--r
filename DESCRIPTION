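Package: eegbandpeak
Title: Band-Peak Spectral Features for Single-Channel EEG Task Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frequency-domain feature extraction and evaluation for
    single-channel electroencephalogram (EEG) mental-task classification.
    Implements band-peak features (the largest alpha-band power spectral
    density peak and the two largest beta-band peaks of a Welch
    periodogram), together with the full evaluation stack around them:
    Butterworth low-pass preprocessing and epoch segmentation, Welch
    spectral estimation, pairwise linear discriminant analysis and
    radial-basis-function support vector machine classification under a
    repeated random-subsampling protocol, receiver operating
    characteristic analysis, and two-level max-win voting for five-class
    decoding.  A seedable synthetic EEG generator with class-dependent
    alpha/beta oscillations over 1/f background noise makes every stage
    testable without access to private recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    jsonlite,
    data.table,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
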