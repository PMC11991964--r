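Package: ApneaScreenR
Title: Sleep-Apnea Screening from Single-Lead ECG with Past/Future Time Windows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Per-minute sleep-apnea detection from single-lead ECG recordings
    using heart-rate-variability and R-peak-amplitude features, assembled with
    past/future time-window context, followed by apnea-hypopnea-index (AHI)
    estimation and sleep-apnea-syndrome screening at AHI >= 5. Includes FIR
    bandpass preprocessing, a Hamilton-style QRS detector, Welch-periodogram
    spectral features, five reference classifiers behind a uniform contract,
    grouped cross-validation, and a synthetic ECG generator with
    apnea-dependent RR and amplitude dynamics for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    ranger,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
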