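Package: phenopipe
Title: Statistical Processing of High-Throughput Plant Phenotyping Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ingests per-plant trait time series exported by 3-D plant
    phenotyping platforms (CSV archives with plant unit coordinates and
    ISO 8601 timestamps), groups near-coincident timestamps into scan-pass
    time clusters with one-dimensional DBSCAN, filters outliers within
    clusters by z-score or interquartile-range rules, logit-transforms
    percentage traits such as spectral-index bins, aggregates technical
    replicates to medians, and runs grouped analyses: descriptive
    statistics, Shapiro-Wilk diagnostics, ANOVA with all two-way
    interactions, Tukey HSD contrasts, and compact letter displays.
    Includes a seeded generator of synthetic factorial experiments with
    known ground truth, and a command-line interface for headless runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    arrow,
    dplyr,
    lubridate,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
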