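Package: pedbkit
Title: Post-Event Deep Breathing Analysis for Obstructive Sleep Apnea
    Polysomnography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies the ventilatory overshoot that follows obstructive
    apneas and hypopneas from overnight airflow recordings.  Detects breaths
    after each annotated respiratory event, averages the peak-to-peak
    amplitudes of the first three post-event deep breaths (PEDB) into a
    per-event series, standardizes series of unequal length onto a common
    grid by exact piecewise-polynomial interpolation, builds group
    characteristic curves with bootstrap confidence bands, selects a
    polynomial regression degree by train/test RMSE, and compares groups
    with dynamic time warping and nonparametric quartile statistics
    (Wilcoxon signed-rank, Mann-Whitney U, per-subject Spearman
    correlations).  Includes a seeded synthetic polysomnography generator
    with annotated events and controllable overnight overshoot trends, plus
    readers/writers for EDF, CSV and NSRR-style annotation XML, so the full
    pipeline is testable without access-controlled sleep-study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    signal,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
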