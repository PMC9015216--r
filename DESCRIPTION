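Package: morphdisp
Title: Natal Dispersal Analysis for Color-Polymorphic Nest-Box Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing natal dispersal distances of color-polymorphic
    birds breeding in finite nest-box networks. Provides nest-box registry
    geometry (planar or geographic coordinates, era-dependent box
    availability), construction of winter-temperature-anomaly and prey-index
    covariates, a randomization test comparing the observed median dispersal
    distance against random settlement over detectable boxes, linear mixed
    models of dispersal distance with crossed random intercepts and
    Satterthwaite denominator degrees of freedom, a binomial GLM of yearly
    morph proportions, and an individual-based simulator of Mendelian
    one-locus color-morph inheritance with morph-by-winter dispersal effects
    for calibration and parameter-recovery studies. All user-facing functions
    take and return tidy data frames.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
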