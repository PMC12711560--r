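Package: wildharvest
Title: Spatially Explicit Estimation of Wild-Meat Harvest, Availability and
    Nutrient Adequacy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate wildlife harvest across a gridded landscape
    from locality-level hunting records: hunter harvest rates (HHR) and
    taxon-specific offtake proportions (TSOP), subsampled random-forest
    ensembles producing quantile surfaces of harvest productivity,
    density-capped individual and biomass offtake accounting, edible-meat
    and per-capita availability surfaces, and population-level dietary
    reference intake (DRI) adequacy. Includes a synthetic-data generator
    with known ground truth for validation, Monte Carlo propagation of
    trait uncertainty, and a reproducible end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
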