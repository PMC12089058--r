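Package: nirsbci
Title: Short-Channel-Corrected fNIRS Brain-Computer Interface Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and classification tools for prefrontal functional
    near-infrared spectroscopy (fNIRS) brain-computer interfaces. Provides a
    seeded generator of synthetic dual-wavelength fNIRS sessions with
    short-channel superficial physiology, Modified Beer-Lambert Law chromophore
    conversion, Butterworth bandpass filtering, recursive-least-squares
    short-channel regression with frozen coefficients, windowed feature
    extraction with ANOVA F-test feature selection, a suite of six classifier
    families with fixed hyperparameter grids, participant-level leave-one-out
    cross-validation with leakage-proof preprocessing, online sliding-window
    replay of a frozen pipeline, and macro-averaged precision/recall/F1
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    class,
    e1071,
    jsonlite,
    nnet,
    randomForest,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
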