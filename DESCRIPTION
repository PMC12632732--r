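Package: mobipipe
Title: Mobile Brain/Body Imaging Analysis for Dual-Task Go/NoGo Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for mobile brain/body imaging (MoBI) experiments
    combining a visual Go/NoGo task, treadmill walking, and optic flow.
    Provides behavioral scoring (signal-detection d-prime and reaction times),
    marker-based gait kinematics (heel-strike and heel-lift detection, stride
    time, stride length, step width and their coefficients of variation),
    event-related potential (ERP) preprocessing and P2/N2/P3 peak extraction,
    pointwise t-statistic cluster analysis with a consecutive-sample run
    criterion, and split-plot repeated-measures ANOVA with Greenhouse-Geisser
    correction. A synthetic-session generator produces time-synchronized
    behavioral, motion-capture, and EEG streams with known ground truth so
    that every stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite
Config/testthat/edition: 3
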