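Package: mealquality
Title: Meal-Level Diet Quality Analysis of Weighed Dietary Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meal-level analysis of multi-day weighed dietary
    records. Classifies diary entries into breakfast, lunch, dinner and
    snack eating occasions (excluding water-only occasions, resolving
    multiple entries per diary section and merging overlapping
    occasions), aggregates nutrient and food-group intakes per meal type
    with zeros for non-consumers, scores diet quality of the total diet
    and of each meal type with the Healthy Eating Index-2015 and the
    Nutrient-Rich Food Index 9.3, screens energy-intake misreporting via
    Goldberg EI:BMR cut-offs, decomposes intakes into per-meal percentage
    contributions, and runs tertile-based covariate-adjusted association
    analyses. A calibrated synthetic-record generator emulates 4-day
    Japanese dietary records so the full pipeline is testable without
    access to survey data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
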