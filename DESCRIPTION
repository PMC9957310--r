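Package: ergofield
Title: Field Ergonomics Pipeline Linking Direct Workload Measures to Perceived-Exertion Scales
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for occupational-physiology field studies that instrument
    workers with 1-Hz heart-rate monitors and 1000-Hz bilateral trapezius
    surface electromyography (EMG) while collecting Borg RPE, Omni RPE and
    Borg CR10 effort ratings over a work shift. Implements heart-rate
    cleaning (5-point moving median), percent heart-rate reserve with its
    square-root normalizing transform, EMG band-pass filtering, per-10-minute
    spectral features (median and mean power frequency, amplitude
    percentiles), PCA-based anomalous-window screening, median-power-frequency
    fatigue slopes per subject and muscle side with a pooled side- and
    subject-adjusted model, baseline-delta coding of the rating scales, and
    the stratified association battery (Pearson and Spearman correlations,
    confounder-adjusted regressions, ANOVA with Tukey HSD, Kruskal-Wallis
    with Dunn post hoc tests). A synthetic-cohort generator with known ground
    truth (programmable heart-rate gain, EMG spectral compression rate and
    rating rank-correlation) makes every stage testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
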