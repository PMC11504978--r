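Package: drakecall
Title: Sex Identification of Ducklings from Their Vocalisations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for determining the sex of one-day-old ducklings from sound
    recordings. Implements the complete signal chain: reading and writing mono
    16-bit PCM WAV audio, pre-emphasis, framing and Hamming windowing,
    voice-activity endpoint detection by thresholding the product of short-term
    energy and zero-crossing rate, extraction of 36-dimensional Mel-frequency
    cepstral coefficient (MFCC) feature vectors (12 static + 12 delta + 12
    delta-delta), three frame-level neural classifiers (a small backpropagation
    network, a deeper dropout-regularised perceptron, and a convolutional
    network), majority-vote aggregation of frame decisions to a per-bird sex
    call, and confusion-matrix evaluation with stratified splits and k-fold
    cross-validation. A seeded generator of duck-call-like recordings with
    sex-specific frequency contours and ground-truth annotations supports
    testing and benchmarking when real recordings are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
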