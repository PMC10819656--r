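Package: vo2kin
Title: Oxygen-Uptake Kinetics and Energy-System Partitioning for
    Breath-by-Breath Gas Exchange
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Clean breath-by-breath gas-exchange recordings (artifact
    exclusion, mean +/- 3 SD retention, breath moving average, temporal
    binning), fit delayed mono- and bi-exponential oxygen-uptake (VO2)
    on- and off-transient kinetics with residual-bootstrap confidence
    intervals, integrate accumulated VO2 and excess post-exercise oxygen
    consumption, and partition total energy expenditure into oxidative,
    glycolytic and phosphagen contributions. Includes cohort-level
    statistics (paired tests, repeated-measures ANOVA with Bonferroni
    post-hoc, Cohen's d) and a synthetic breath-by-breath data generator
    for validation studies of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    zoo
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
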