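Package: nutridense
Title: Nutrient Profiling of Plant-Based Milk Alternatives and Waters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for assessing the nutrient density of
    plant-based (PB) milk alternatives and PB waters from branded-food label
    data. Reads USDA FoodData Central style branded-food tables, mines
    ingredient statements for added sugars, added sodium and fortificants,
    classifies each beverage by its main plant source, imputes undeclared
    vitamin values from category medians, checks products against proposed
    per-100 g nutrient standards, and scores them with the Nutrient Rich Food
    index (NRF5.3), the 2017 Nutri-Score point algorithm in both its solid-food
    and beverage modes, and the Choices International beverage criteria.
    Includes group summary statistics (one-way ANOVA with Bonferroni post hoc
    tests, Spearman correlations, paired t-tests) and a synthetic cohort
    generator calibrated to published category-level means so the whole
    pipeline is testable without the full database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
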