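Package: holterhrv
Title: Holter ECG Intervals, Ventricular Ectopy Grading and Heart Rate
    Variability Analysis from Annotated Beat Streams
Version: 0.1.0
Authors@R:
    person("Holter", "HRV Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analyses annotated Holter beat streams (R-peak times, beat
    labels, optional wave fiducials) from long ambulatory ECG recordings:
    extraction of normal-to-normal (NN) intervals with arrhythmia-adjacent
    exclusion, trace-level HR/PR/QT summaries with four heart-rate QT
    corrections (Bazett, Fridericia, Van de Water, Matsunaga) and a
    data-driven correction-selection procedure, ventricular ectopy
    quantification with Lown severity grading, time-domain and Poincare
    (SD1/SD2) heart-rate-variability indices, Welch-averaged RR-tachogram
    spectral band powers (VLF/LF/HF), and longitudinal cohort statistics
    (pooled-variance LSD group contrasts, Spearman screens of early indices
    against a late echocardiographic outcome). Includes an integral-pulse
    frequency-modulation (IPFM) beat-stream and cohort simulator so every
    stage is verifiable by parameter recovery without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
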