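Package: decatr
Title: Simulation and Analysis of Single-Molecule DNA Braid Decatenation Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for magnetic-tweezers experiments in which two braided DNA
    tethers are decatenated by a type IA topoisomerase. Provides a geometric
    model of the braid (crossover angle, extension versus catenation number,
    equipartition force calibration), a stochastic generator of decatenation
    event schedules rendered into noisy bead-extension traces, a
    segmentation pipeline that recovers decatenation runs and the five
    per-experiment kinetic features (initial and secondary time lags, run
    sizes, per-run rates, total decatenation rate), exponential dwell-time
    histogram fitting, cohort statistics, and crossover-angle
    classification. All user-facing functions take and return tibbles so
    analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
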