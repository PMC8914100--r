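Package: isapac
Title: Infraslow EEG Phase-Amplitude Coupling and Coherence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for infraslow (0.01-0.1 Hz) brain activity
    and its coupling to peripheral arousal signals such as the galvanic
    skin response (GSR) and respiration. Provides zero-phase band
    filtering and Hilbert phase/envelope extraction at the native
    sampling rate, instantaneous-frequency estimation, phase-binned
    coupling quantified by a d-prime discriminability index with per-bin
    t-tests, inter-channel and inter-trial phase coherence with
    permutation nulls, lag scans between cortical and peripheral phase
    series, group-comparison machinery (median splits, per-time-point
    tests), a ground-truth synthetic session generator, and EDF/BDF plus
    BIDS-style events readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
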