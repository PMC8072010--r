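Package: rowforage
Title: Behavioral Analysis of Virtual-Navigation Foraging Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for human virtual-navigation foraging sessions
    (Restaurant-Row-style "Movie Row" and "Candy Row" tasks): per-category delay
    thresholds by padded leave-one-out Heaviside fits, vicarious trial-and-error
    (VTE) offer-zone trajectory metrics (latency, rotation, reversals, pausing,
    distance, entry bias) with the task's exclusion and normalization rules,
    regret and choice-sequence trial labeling, sunk-cost analyses (conditional
    completion curves and entry-bias choice models), and hyperbolic
    delay-discounting survey scoring. Includes a synthetic-agent simulator with
    known ground-truth parameters so every estimator is testable by parameter
    recovery without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
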