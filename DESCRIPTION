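Package: egodelay
Title: Egocentric Network Analysis of Delayed Hospital Arrival After Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse personal (egocentric) social networks of stroke
    patients in relation to delayed hospital arrival. Computes structural-hole
    measures (Burt constraint, effective size, mean degree) and compositional
    diversity measures (percent kin, age spread, index of qualitative variation)
    from survey-derived alter rosters and tie lists; runs cohort-level group
    comparisons, covariate-adjusted block-wise logistic regressions per network
    metric, and sensitivity analyses (alternative time cutoff, small-network
    removal, race stratification and interaction); and generates calibrated
    synthetic two-group cohorts so the whole pipeline is testable without
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
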