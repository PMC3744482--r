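Package: ordertrans
Title: Dynamic Complexity and Order Transitions in Psychotherapy Process Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis of discontinuous change in psychotherapy from daily
    self-report time series. Computes windowed dynamic complexity (the
    product of a fluctuation-intensity measure and a distribution measure
    over a known theoretical scale range), detects order transitions at
    maxima of the item-averaged complexity curve, labels inter-scan
    intervals as containing a transition (OT), not containing one (NOT),
    or belonging to untreated controls (ISI), and contrasts
    region-of-interest brain activation changes across interval types
    with paired and Welch t tests, exact Wilcoxon tests, point-biserial
    effect sizes, Type-III interaction ANOVA and BCa bootstrap intervals.
    Includes seeded generators for synthetic rating cohorts and ROI
    activation panels with known ground truth, and a pipeline driver that
    runs the whole study end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    boot,
    car,
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
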