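Package: foragedive
Title: Predicting Marine-Predator Foraging Success from Dive Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for inferring foraging success of diving marine predators
    from time-depth-recorder and jaw-mounted accelerometer data. Provides
    surface-offset correction, dive detection and descent/bottom/ascent phase
    segmentation, detection of steps and wiggles in dive profiles,
    maximum-likelihood dive-bout delimitation, prey-capture-attempt detection
    from high-frequency jaw acceleration, multi-scale aggregation of
    predictors (dive, bout, fixed windows, night), all-subsets Poisson
    mixed-model selection with AICc model averaging, and
    leave-one-individual-out concordance validation. A ground-truthed
    synthetic-data generator emulates multi-day foraging trips so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    lme4,
    survival,
    testthat (>= 3.0.0),
    withr,
    zoo
Config/testthat/edition: 3
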