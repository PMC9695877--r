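#' Published category-level nutrient parameters for PB beverages
#'
#' Category-level sample sizes, mean nutrient contents per 100 g and standard
#' errors of the mean for the 2021 USDA branded-food plant-based beverage
#' cohort, as published in category summary tables. These are the default
#' calibration of the synthetic cohort generator: per-category SDs are
#' recovered as SE x sqrt(n). The energy column is published without an SE;
#' the generator assumes a coefficient of variation for energy (see
#' [synthetic_config()]).
#'
#' @param type `"milk"` for PB milk alternatives, `"water"` for PB waters.
#' @return Tibble with `category`, `n`, `energy_mean`, and `<var>_mean` /
#'   `<var>_se` pairs for protein, total sugars, total fat, saturated fat,
#'   calcium and sodium.
#' @export
pb_reference_parameters <- function(type = c("milk", "water")) {
  type <- match.arg(type)
  if (type == "milk") {
    tibble::tribble(
      ~category,     ~n,   ~energy_mean, ~protein_mean, ~protein_se, ~sugars_mean, ~sugars_se, ~fat_mean, ~fat_se, ~satfat_mean, ~satfat_se, ~calcium_mean, ~calcium_se, ~sodium_mean, ~sodium_se,
      "almond",      407L, 27,  0.71, 0.04, 2.58, 0.14, 1.37, 0.04, 0.06, 0.01, 128.6, 3.79,  62.4, 0.81,
      "cashew",      38L,  36,  0.87, 0.11, 1.88, 0.30, 2.26, 0.25, 0.40, 0.09, 66.8,  12.64, 43.2, 4.30,
      "coconut",     243L, 95,  0.70, 0.05, 2.12, 0.14, 8.66, 0.43, 7.43, 0.38, 23.7,  3.34,  26.5, 1.31,
      "flax_hemp",   30L,  37,  1.46, 0.23, 3.00, 0.51, 1.64, 0.15, 0.11, 0.03, 104.9, 11.22, 41.3, 3.03,
      "macadamia",   15L,  27,  0.31, 0.05, 1.29, 0.36, 2.29, 0.33, 0.42, 0.07, 166.6, 9.67,  44.0, 2.02,
      "walnut",      8L,   33,  0.63, 0.14, 2.60, 0.93, 2.00, 0.57, 0.10, 0.07, 101.6, 25.67, 47.1, 7.70,
      "rice",        28L,  53,  0.50, 0.07, 5.05, 0.51, 1.21, 0.13, 0.17, 0.09, 101.4, 10.68, 36.2, 1.77,
      "quinoa",      3L,   34,  0.84, 0.00, 1.97, 1.13, 0.42, 0.00, 0.00, 0.00, 127.0, 0.00,  46.0, 0.00,
      "soy",         147L, 44,  2.82, 0.05, 3.62, 0.19, 1.52, 0.03, 0.20, 0.01, 116.9, 4.94,  43.0, 1.37,
      "oat",         74L,  53,  1.35, 0.08, 4.15, 0.39, 1.90, 0.15, 0.43, 0.11, 108.3, 7.79,  49.0, 1.75,
      "pea",         23L,  46,  3.46, 0.08, 3.44, 0.58, 1.93, 0.10, 0.20, 0.02, 180.0, 9.00,  47.8, 3.27,
      "tree_nut",    18L,  41,  1.01, 0.22, 3.51, 0.70, 2.29, 0.30, 0.42, 0.14, 68.3,  14.61, 47.3, 3.95,
      "seeds_fruit", 8L,   42,  1.68, 0.51, 3.18, 1.43, 2.01, 0.27, 0.31, 0.11, 99.2,  17.20, 33.1, 6.36
    )
  } else {
    tibble::tribble(
      ~category,        ~n,   ~energy_mean, ~protein_mean, ~protein_se, ~sugars_mean, ~sugars_se, ~fat_mean, ~fat_se, ~satfat_mean, ~satfat_se, ~calcium_mean, ~calcium_se, ~sodium_mean, ~sodium_se,
      "coconut",        464L, 23, 0.08, 0.02, 4.72, 0.08, 0.09, 0.02, 0.06, 0.01, 13.9, 2.04,  23.38, 0.57,
      "aloe",           36L,  21, 0.00, 0.00, 4.71, 0.60, 0.00, 0.00, 0.00, 0.00, 8.9,  2.04,  7.33,  1.21,
      "tree",           23L,  12, 0.00, 0.00, 2.64, 0.30, 0.00, 0.00, 0.00, 0.00, 5.8,  0.81,  2.70,  1.18,
      "fruit",          15L,  23, 0.09, 0.05, 4.87, 1.30, 0.00, 0.00, 0.00, 0.00, 5.1,  1.52,  8.87,  1.99,
      "plain_flavored", 12L,  12, 0.03, 0.03, 3.29, 0.88, 0.10, 0.10, 0.00, 0.00, 18.5, 15.52, 7.50,  6.19
    )
  }
}

#' Configuration for the synthetic cohort generator
#'
#' The generator emulates a branded-food beverage cohort: per-category
#' nutrient values drawn from a gamma family moment-matched to the published
#' category (mean, SD = SE x sqrt(n)); ingredient statements assembled in
#' order of predominance (water, plant base, then sweetener, salt and
#' fortificant terms drawn with the configured prevalences); and a configured
#' fraction of vitamin fields blanked to exercise the imputation path.
#'
#' Default prevalences are the published cohort-level rates where one was
#' printed in the text (added sugars 51% of milk alternatives; vitamin C in
#' about 25% of waters; fortificant counts out of 1042 milk alternatives:
#' calcium 672, vitamin D 648, vitamin A 620, vitamin B12 344, vitamin E 210,
#' zinc 110, rounded to 0.65/0.60/0.60/0.35/0.20/0.10) and documented round
#' numbers otherwise (salt 0.80 for milks, 0.20 for waters; sweetened waters
#' 0.60; energy CV 0.25; vitamin missingness 0.15). Per-category nutrient
#' correlations are not modeled (independent draws).
#'
#' @param type `"milk"` or `"water"`.
#' @param categories Parameter tibble, see [pb_reference_parameters()]; the
#'   `n` column may be edited to scale the cohort.
#' @param sweetened_prob,salted_prob Probabilities in \[0, 1\].
#' @param fortified_prob Named probabilities per fortificant nutrient.
#' @param missingness_prob Probability that a vitamin A/D/B12 value is
#'   blanked (`NA`) on the label data.
#' @param energy_cv Coefficient of variation assumed for energy density.
#' @param seed Integer seed; generation is deterministic given the config.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(type = c("milk", "water"),
                             categories = pb_reference_parameters(type),
                             sweetened_prob = if (type == "milk") 0.51 else 0.60,
                             salted_prob = if (type == "milk") 0.80 else 0.20,
                             fortified_prob = NULL,
                             missingness_prob = 0.15,
                             energy_cv = 0.25,
                             seed = 1L) {
  type <- match.arg(type)
  if (is.null(fortified_prob)) {
    fortified_prob <- if (type == "milk") {
      c(calcium = 0.65, vitamin_a = 0.60, vitamin_d = 0.60, vitamin_e = 0.20,
        vitamin_c = 0.02, vitamin_b12 = 0.35, zinc = 0.10)
    } else {
      c(calcium = 0.05, vitamin_a = 0.02, vitamin_d = 0.00, vitamin_e = 0.02,
        vitamin_c = 0.25, vitamin_b12 = 0.02, zinc = 0.00)
    }
  }
  probs <- c(sweetened_prob, salted_prob, fortified_prob, missingness_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]",
                                       call. = FALSE)
  stopifnot(all(categories$n >= 0), energy_cv >= 0)
  structure(
    list(type = type, categories = categories, sweetened_prob = sweetened_prob,
         salted_prob = salted_prob, fortified_prob = fortified_prob,
         missingness_prob = missingness_prob, energy_cv = energy_cv,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Gamma draws with exact mean/SD on nonnegative support; degenerate cases
# (sd = 0 or mean = 0) return constants.
rgamma_mv <- function(n, mean, sd) {
  if (mean <= 0) return(rep(0, n))
  if (sd <= 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, scale = sd^2 / mean)
}

synthetic_base_phrases <- function() {
  list(
    milk = c(almond = "almonds", cashew = "cashews", coconut = "coconut cream",
             flax_hemp = "cold pressed flax oil", macadamia = "macadamia nuts",
             walnut = "walnuts", rice = "rice", quinoa = "quinoa",
             soy = "organic soy", oat = "oats", pea = "pea protein",
             tree_nut = "pistachios", seeds_fruit = "sunflower seeds"),
    water = c(coconut = "coconut water", aloe = "aloe vera juice",
              tree = "maple sap", fruit = "watermelon juice",
              plain_flavored = "natural flavors")
  )
}

synthetic_long_names <- function() {
  list(
    milk = c(almond = "Almond milk", cashew = "Cashew milk",
             coconut = "Coconut milk beverage", flax_hemp = "Flax milk",
             macadamia = "Macadamia milk", walnut = "Walnut milk",
             rice = "Rice drink", quinoa = "Quinoa beverage",
             soy = "Soy milk", oat = "Oat milk", pea = "Pea milk",
             tree_nut = "Pistachio milk", seeds_fruit = "Sunflower milk"),
    water = c(coconut = "Coconut water", aloe = "Aloe water",
              tree = "Maple water", fruit = "Watermelon water",
              plain_flavored = "Flavored botanical water")
  )
}

fortificant_phrases <- function() {
  c(calcium = "tricalcium phosphate", vitamin_a = "vitamin a palmitate",
    vitamin_d = "ergocalciferol (vitamin d2)",
    vitamin_e = "alpha-tocopherol acetate", vitamin_c = "ascorbic acid",
    vitamin_b12 = "cyanocobalamin (vitamin b12)", zinc = "zinc oxide")
}

# Fortified-product vitamin amounts per 100 g: documented round-number
# assumptions consistent with typical US fortification levels.
fortified_amounts <- function() {
  list(vit_a_iu = c(160, 40), vit_d_iu = c(42, 10), vit_b12_mcg = c(0.63, 0.25),
       vit_e_mg = c(1.5, 0.5), vit_c_mg = c(6, 2), zinc_mg = c(0.35, 0.1))
}

#' Generate a synthetic PB milk-alternative cohort
#'
#' Draws `n` products per category with nutrient values from the
#' moment-matched gamma family, assembles label-style ingredient statements
#' in order of predominance (filtered water, the plant base, then sweetener,
#' salt and fortificant terms with the configured prevalences), links
#' vitamin amounts to the fortification indicators (unfortified products get
#' 0), and blanks a configured fraction of vitamin A/D/B12 values so the
#' imputation stage has work to do. Deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A product tibble in the canonical schema (see [load_flat()]).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  bases <- synthetic_base_phrases()[[config$type]]
  names_map <- synthetic_long_names()[[config$type]]
  fort_phr <- fortificant_phrases()
  amounts <- fortified_amounts()
  sweeteners <- c("organic cane sugar", "cane sugar", "brown rice syrup", "honey")
  usda_cat <- if (config$type == "milk") "pb_milk_alternative" else "pb_water"

  rows <- purrr::pmap(config$categories, function(category, n, energy_mean,
                                                  protein_mean, protein_se,
                                                  sugars_mean, sugars_se,
                                                  fat_mean, fat_se,
                                                  satfat_mean, satfat_se,
                                                  calcium_mean, calcium_se,
                                                  sodium_mean, sodium_se, ...) {
    if (n == 0L) return(NULL)
    sd_of <- function(se) se * sqrt(n)
    df <- tibble::tibble(
      product_id = paste0("syn_", config$type, "_", category, "_", seq_len(n)),
      long_name = paste(names_map[[category]], seq_len(n)),
      brand = paste0("Brand ", toupper(substr(category, 1, 2))),
      usda_category = usda_cat,
      energy_kcal_100g = rgamma_mv(n, energy_mean, energy_mean * config$energy_cv),
      protein_g = rgamma_mv(n, protein_mean, sd_of(protein_se)),
      total_fat_g = rgamma_mv(n, fat_mean, sd_of(fat_se)),
      satfat_g = rgamma_mv(n, satfat_mean, sd_of(satfat_se)),
      total_sugars_g = rgamma_mv(n, sugars_mean, sd_of(sugars_se)),
      fiber_g = if (config$type == "milk") rgamma_mv(n, 0.5, 0.4) else rep(0, n),
      calcium_mg = rgamma_mv(n, calcium_mean, sd_of(calcium_se)),
      sodium_mg = rgamma_mv(n, sodium_mean, sd_of(sodium_se))
    )
    sweet <- stats::runif(n) < config$sweetened_prob
    salted <- stats::runif(n) < config$salted_prob
    fort <- vapply(config$fortified_prob,
                   function(p) stats::runif(n) < p,
                   logical(n)) |> matrix(nrow = n,
                                         dimnames = list(NULL, names(config$fortified_prob)))
    draw_amt <- function(col, on) {
      a <- amounts[[col]]
      ifelse(on, rgamma_mv(n, a[1], a[2]), 0)
    }
    df$vit_a_iu <- draw_amt("vit_a_iu", fort[, "vitamin_a"])
    df$vit_d_iu <- draw_amt("vit_d_iu", fort[, "vitamin_d"])
    df$vit_b12_mcg <- draw_amt("vit_b12_mcg", fort[, "vitamin_b12"])
    df$vit_e_mg <- draw_amt("vit_e_mg", fort[, "vitamin_e"])
    df$vit_c_mg <- draw_amt("vit_c_mg", fort[, "vitamin_c"])
    df$zinc_mg <- draw_amt("zinc_mg", fort[, "zinc"])
    df$riboflavin_mg <- rgamma_mv(n, 0.1, 0.05)
    # calcium fortification raises no extra amount: the category calcium
    # distribution already reflects the fortified market mix
    for (v in c("vit_a_iu", "vit_d_iu", "vit_b12_mcg")) {
      blank <- stats::runif(n) < config$missingness_prob
      df[[v]][blank] <- NA_real_
    }
    sweet_term <- sample(sweeteners, n, replace = TRUE)
    df$ingredients_text <- vapply(seq_len(n), function(i) {
      parts <- c("filtered water", bases[[category]])
      if (sweet[i]) parts <- c(parts, sweet_term[i])
      if (salted[i]) parts <- c(parts, "sea salt")
      parts <- c(parts, "gellan gum")
      on <- names(config$fortified_prob)[fort[i, ]]
      parts <- c(parts, unname(fort_phr[on]))
      paste(parts, collapse = ", ")
    }, character(1))
    df$generated_sweetened <- sweet
    df$generated_salted <- salted
    for (nm in colnames(fort)) df[[paste0("generated_fort_", nm)]] <- fort[, nm]
    df
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- generate_cohort(synthetic_config(
      config$type,
      categories = dplyr::mutate(config$categories[1, ], n = 1L),
      seed = config$seed))[0, ]
    return(out)
  }
  truth_cols <- grep("^generated_", names(out), value = TRUE)
  structure(out[, c(product_columns(), truth_cols)],
            generator_truth = truth_cols)
}

#' Generate a synthetic PB water cohort
#'
#' Convenience wrapper: [generate_cohort()] with a water-type configuration
#' (near-zero protein and fats, water-subtype ingredient bases, vitamin C as
#' the dominant fortificant).
#'
#' @param config A water-type [synthetic_config()]; defaults to
#'   `synthetic_config("water")`.
#' @return A product tibble.
#' @export
generate_waters <- function(config = synthetic_config("water")) {
  stopifnot(identical(config$type, "water"))
  generate_cohort(config)
}

#' Write a synthetic cohort to a flat CSV
#'
#' Drops the `generated_*` ground-truth columns and writes the canonical flat
#' schema consumable by [load_flat()].
#'
#' @param cohort Output of [generate_cohort()].
#' @param path Destination CSV.
#' @return Invisibly, the path.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort[, product_columns()], path, na = "")
  invisible(path)
}
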