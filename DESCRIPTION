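Package: wradiet
Title: Dietary Diversity and Micronutrient Adequacy from Household 24-Hour Recalls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for assessing the diet quality of women of
    reproductive age from household-level 24-hour dietary recall surveys.
    Resolves food codes against a food composition table with ordered
    fallback sources, allocates household nutrient totals to individuals
    with adult-male-equivalent (AME) consumption units, scores per-nutrient
    adequacy (nutrient adequacy ratio, mean adequacy ratio, EAR cut-point
    inadequacy prevalence, tolerable-upper-level exceedance), computes the
    Minimum Dietary Diversity for Women (MDD-W) indicator over the ten FAO
    food groups with the 15-gram rule, and fits logistic and linear models
    for the socio-economic determinants of MDD-W and of micronutrient
    adequacy. Includes a seeded synthetic-survey generator with ground
    truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    stats,
    utils,
    car
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
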