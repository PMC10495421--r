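Package: emodyn
Title: Aggregate Emotion Dynamics via Appraisal-Structured Vector Autoregression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Models the day-to-day flow of emotions expressed in large
    document collections (for example social-media conversations) with a
    restricted VARX(1) whose intercepts, carryover and cross-lagged
    transition coefficients are functions of the emotions' positions in an
    appraisal space (valence, arousal, dominance), estimated by feasible
    generalized least squares on daily emotion-frequency panels.  Provides
    lexicon-based document labeling and daily aggregation, reduction of
    appraisal surveys to factor scores, asymmetric appraisal-space
    distances, pre-estimation diagnostics (augmented Dickey-Fuller tests,
    lag-order selection, Granger causality), duration intervals,
    covariance-implied shock vectors, impulse-response and cumulative
    impulse-response analysis, distance regressions for co-occurrence and
    long-term transition patterns, and a fully seeded synthetic-data
    generator for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
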