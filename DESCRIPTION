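Package: phenofp
Title: Flowering-Potential Profiles for Grassland Nutrient-Addition Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes monthly flowering-potential (FP) profiles for plant
    communities surveyed as plot-level percent cover, by distributing each
    species' relative cover across the months its published flora reports it
    in flower. Supports total-community profiles and provenance
    (native/exotic) and functional-group (C3/C4 graminoid, forb, legume)
    subsets, the area-under-curve flowering volume, and the factorial
    NPK(+micronutrient) mixed-model analysis (nutrients x month x ecoregion
    fixed effects, block nested in site random effects) with
    Bonferroni-corrected nitrogen contrasts by month. Includes a synthetic
    NutNet-style data generator with known injected effect structure for
    calibration and power checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    nlme,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    emmeans,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
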