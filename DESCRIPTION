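Package: pgesr
Title: Detection of Post-Ictal Generalised EEG Suppression from Two-Channel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting Post-Ictal Generalised EEG Suppression (PGES)
    and estimating its duration from two-channel EEG recordings such as those
    produced by subcutaneous devices. Provides EDF and tabular recording I/O
    with bipolar re-referencing and seizure-segment excision, a preprocessing
    chain (resampling to 207 Hz, zero-phase 8th-order Butterworth band-pass
    0.5-45 Hz, 50 Hz notch), extraction of 14 per-epoch features (rectified
    time-domain statistics, absolute and relative band powers, Petrosian
    fractal dimension), a variational auto-encoder anomaly detector trained
    with the Adam optimiser, threshold calibration by F1 scan, sliding-window
    majority-flip smoothing of epoch predictions, run-length duration
    estimation, evaluation metrics, and a synthetic annotated EEG cohort
    generator so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
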