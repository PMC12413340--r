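Package: phasesleep
Title: EEG Phase-Coupling Connectivity and NREM Sleep-Stage Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes six Hilbert-based phase-coupling metrics (coherence,
    imaginary coherency, phase-locking value, corrected imaginary PLV, phase
    lag index, weighted phase lag index) on band-pass filtered multichannel
    EEG in 10 s epochs, tests stage differences with Friedman and Nemenyi
    nonparametric statistics under Bonferroni control, and classifies AASM
    sleep stages (W, N1, N2, N3) from connectivity feature vectors with
    subject-wise gradient-boosted tree classification. Includes a synthetic
    cohort generator with stage- and band-dependent inter-channel phase
    coupling under volume-conduction-like mixing, so the full pipeline is
    testable without clinical recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    xgboost,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
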