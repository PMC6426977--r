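Package: dynstab
Title: Dynamical-Stability Analysis and State Classification of Multichannel Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed first-order vector-autoregressive (VAR(1)) fits of
    multichannel electrophysiological recordings, eigenvalue-to-mode mapping
    (frequency and damping timescale), coarse-grained dynamical-stability (DS)
    feature vectors, spectral (FFT) baseline vectors, surrogate controls
    (phase randomization, per-channel staggering), Kolmogorov-Smirnov tracking
    of stabilization over time, and linear-SVM classification of awake versus
    anesthetized brain state with ROC/AUC evaluation. Includes a synthetic
    generator of noise-driven linear systems with designed eigenstructure for
    end-to-end validation of the pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
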