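Package: facegamma
Title: Intracranial EEG Analysis of Face-Evoked Potentials, Gamma Power
    and Cross-Regional Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing face-evoked responses in intracranial EEG
    recordings from mesial temporal structures. Implements the full chain
    from raw multichannel recordings (EDF) and stimulus event tables to
    event-related potential peak amplitudes, induced gamma-band power via
    Morlet wavelet decomposition with decibel baselining, two-group
    cluster-based permutation statistics on time-frequency maps,
    inter-regional phase-amplitude coupling comodulograms with surrogate
    z-scores, cross-frequency phase-slope-index directionality, and
    trial-level linear mixed-effects group models with Holm-Bonferroni
    correction. Ships a synthetic two-group iEEG study generator that
    emulates the stimulation paradigm (six picture categories, jittered
    interstimulus intervals, 1/f background, evoked deflections, induced
    gamma bursts, lagged cross-regional coupling) so every stage is testable
    without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lme4,
    lmerTest,
    emmeans,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
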