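Package: eegpheno
Title: Sleep and Auditory EEG Phenotyping for Mouse Disease Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of chronic mouse EEG/EMG phenotyping
    experiments: rule-based sleep staging (WAKE/NREM/REM) on 10-s epochs,
    resting-state spectral analysis (Welch band power, spectral entropy,
    aperiodic 1/f parameterization, Tort phase-amplitude modulation index),
    sleep-spindle detection at 9/11/13/15 Hz, auditory steady-state response
    (ASSR) entrainment power ratios, mismatch-negativity (MMN) event-related
    potentials, and genotype group statistics (one-way ANOVA with Tukey HSD).
    Includes a ground-truthed synthetic EEG/EMG session generator with
    injectable genotype effects so that every pipeline stage is testable
    without animal data, plus EDF signal I/O and a study orchestrator.
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
    jsonlite
Config/testthat/edition: 3
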