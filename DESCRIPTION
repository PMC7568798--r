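Package: scatbeat
Title: Wavelet Scattering Features for ECG Heartbeat Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Classifies single ECG heartbeats into the four AAMI EC57
    arrhythmia classes (nonectopic, supraventricular ectopic, ventricular
    ectopic, fusion) using a two-order wavelet scattering transform.
    Provides Gabor (analytic Morlet) filter-bank construction, the
    scattering cascade with critical downsampling, readers and writers for
    WFDB records and annotations, AAMI beat-symbol mapping and fixed-window
    beat segmentation, class balancing by Gaussian-noise augmentation,
    dimensionality reduction of the scattering time windows (window
    selection and per-node first principal component), k-nearest-neighbour,
    probabilistic-neural-network and feedforward-network classifiers, and
    AAMI-style cross-validated evaluation with per-class and
    normal-versus-abnormal metrics. A synthetic heartbeat generator makes
    the whole pipeline testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    class,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
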