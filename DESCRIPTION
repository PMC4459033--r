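Package: thetaPLF
Title: Theta Phase Alignment and Cross-Frequency Coupling in Epoched
    Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for stimulus-locked phase dynamics in epoched
    multi-channel electrophysiology. Computes the phase-locking factor
    (inter-trial phase alignment index) on Morlet time-frequency
    decompositions, contrasts conditions with cluster-size permutation tests,
    quantifies theta-gamma phase-amplitude coupling with a surrogate-normalised
    Canolty-style modulation index, derives event-related potentials, and runs
    a participant-level correlation battery with Benjamini-Hochberg FDR
    control and Fisher z comparison of correlations. Includes a fully seeded
    synthetic-cohort generator (von Mises phase resets over 1/f background)
    so every stage is testable end to end without patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    rhdf5,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
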