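Package: benthind
Title: Complementarity, Sensitivity and Specificity of Benthic State Indicators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes 18 benthic state indicators (whole-community abundance
    and biomass, diversity indices, AMBI-family biotic indices, and
    trait-based trawling-sensitivity indices) from long-format community
    samples and a taxon trait table, and evaluates the indicator suite along
    anthropogenic pressure gradients: rank-correlation complementarity with
    Ward clustering, low- versus high-trawling log response-ratio
    random-effects meta-analysis (overall and by sampling gear), and per
    gradient AIC-based trend classification for trawl and non-trawl
    (eutrophication, oxygen depletion, pollution) pressures. Includes a
    seeded synthetic gradient generator so the full comparison runs without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    metafor,
    mgcv,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
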