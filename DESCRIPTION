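Package: earbci
Title: Simulation and Decoding Pipelines for In-Ear EEG Brain-Computer
    Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Signal-processing and decoding pipelines for in-ear
    electroencephalography (EEG) brain-computer interfaces. Implements
    steady-state visual evoked potential (SSVEP) target identification by
    task-related component analysis (TRCA) and filter-bank canonical
    correlation analysis (FBCCA), narrow-band signal-to-noise ratio and
    information-transfer-rate metrics, and cocktail-party auditory
    attention decoding by forward and backward temporal-response-function
    (TRF) modeling. Ships a synthetic-EEG generator (SSVEP trials with
    harmonic structure, resting alpha rhythm, and two-speaker cocktail
    trials built from ground-truth TRFs) so every stage of the pipeline is
    testable end to end without recorded data, plus minimal European Data
    Format (EDF) and delimited-text I/O for continuous recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
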