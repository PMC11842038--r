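Package: ramefr
Title: Envelope-Following Response Markers of Cochlear Synaptopathy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying cochlear-synaptopathy-sensitive
    envelope-following responses (EFRs) from epoched EEG recordings.
    Synthesizes sinusoidally (SAM) and rectangularly (RAM) amplitude-modulated
    tone stimuli with peak-to-peak level matching, estimates the EFR amplitude
    by bootstrapped complex-spectrum averaging with per-harmonic noise-floor
    subtraction and phase-preserving time-domain reconstruction, extracts
    distortion-product otoacoustic emission (DPOAE) thresholds from growth
    functions via a monotonicity-constrained bootstrapped cubic fit, and runs
    the cohort-level statistical battery (correlation-method gating,
    partially-overlapping-samples t-test, residualized speech-reception
    thresholds, multiple regression with diagnostics, commonality variance
    decomposition, piecewise growth fits). Includes synthetic-data generators
    with known ground truth for epoched EEG-like responses, DPOAE growth
    functions, adaptive speech-reception-threshold tracks, and multivariate
    listener cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    utils,
    signal,
    jsonlite,
    car,
    lmtest
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
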