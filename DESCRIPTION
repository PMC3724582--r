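Package: facialemg
Title: Facial EMG Gesture Recognition with Elliptic Basis Function Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for surface electromyogram (sEMG) based facial gesture
    recognition. Provides a seeded synthetic facial-EMG generator
    (band-limited, amplitude-modulated Gaussian signals over three recording
    channels), zero-phase band-pass preprocessing and non-overlapping
    windowing, ten time-domain features (IEMG, MAV, MAVS, MPV, RMS, SSI, VAR,
    MV, WL, SSC), histogram mutual-information estimation with
    minimum-redundancy-maximum-relevance (mRMR) and recognition-accuracy
    feature ranking, and a versatile elliptic basis function neural network
    (VEBF) classifier that learns in a single epoch through recursive mean and
    covariance updates with eigenbasis rotation and neuron merging. Includes a
    full experiment driver producing accuracy, per-gesture and confusion-matrix
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
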