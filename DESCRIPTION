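Package: spindlelat
Title: Sleep Oscillation Lateralization and Emotional Recognition Memory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An overnight polysomnography analysis pipeline for studying how
    lateralized sleep oscillations relate to emotional recognition memory.
    Detects fast (13-16 Hz) sleep spindles with channel-wise amplitude
    thresholds and slow oscillations (0.2-1.25 Hz) with a zero-crossing
    algorithm in NREM EEG, computes slow-oscillation/spindle coupling phase
    via the Hilbert transform, standardized REM theta band power, and
    right-versus-left lateralization indices. Scores three-alternative
    (recollected/familiar/new) recognition responses into signal-detection d'
    over repeated retrievals, and fits the repeated-measures ANOVA/ANCOVA
    models linking oscillatory covariates to memory performance. Includes a
    synthetic polysomnography and response generator with known ground truth
    for validating every stage, plus EDF, hypnogram, artifact and event-table
    input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
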