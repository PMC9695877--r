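#' @keywords internal
"_PACKAGE"

## usethis namespace: start
#' @importFrom rlang .data
## usethis namespace: end
NULL

# Canonical per-100 g product schema. Order is the documented column order of
# every flat CSV this package reads or writes.
product_columns <- function() {
  c("product_id", "long_name", "brand", "usda_category",
    "energy_kcal_100g", "protein_g", "total_fat_g", "satfat_g",
    "total_sugars_g", "fiber_g", "calcium_mg", "sodium_mg",
    "vit_a_iu", "vit_d_iu", "vit_b12_mcg", "vit_c_mg", "vit_e_mg",
    "zinc_mg", "riboflavin_mg", "ingredients_text")
}

nutrient_columns <- function() {
  setdiff(product_columns(),
          c("product_id", "long_name", "brand", "usda_category", "ingredients_text"))
}

#' Unit conversion factors
#'
#' Factors used when normalizing branded-food nutrient units to the canonical
#' per-100 g schema: kcal to kJ (4.184), vitamin D mcg to IU (40), and a
#' configurable vitamin A mcg RAE to IU factor (default 3.33, the
#' retinyl-ester assumption consistent with "vitamin A palmitate" fortificant
#' labels; the appropriate factor depends on the vitamin A form).
#'
#' @param vit_a_iu_per_mcg_rae IU per mcg RAE for vitamin A (> 0).
#' @return Named list of positive conversion factors.
#' @export
unit_conversions <- function(vit_a_iu_per_mcg_rae = 3.33) {
  stopifnot(vit_a_iu_per_mcg_rae > 0)
  list(kcal_to_kj = 4.184, vit_d_mcg_to_iu = 40,
       vit_a_mcg_rae_to_iu = vit_a_iu_per_mcg_rae)
}

# FoodData Central nutrient ids -> (canonical column, expected unit)
fdc_nutrient_map <- function() {
  tibble::tribble(
    ~nutrient_id, ~column,             ~unit,
    1008L,        "energy_kcal_100g",  "KCAL",
    1003L,        "protein_g",         "G",
    1004L,        "total_fat_g",       "G",
    1258L,        "satfat_g",          "G",
    2000L,        "total_sugars_g",    "G",
    1079L,        "fiber_g",           "G",
    1087L,        "calcium_mg",        "MG",
    1093L,        "sodium_mg",         "MG",
    1104L,        "vit_a_iu",          "IU",
    1106L,        "vit_a_iu",          "UG_RAE",
    1110L,        "vit_d_iu",          "IU",
    1114L,        "vit_d_iu",          "UG",
    1178L,        "vit_b12_mcg",       "UG",
    1162L,        "vit_c_mg",          "MG",
    1109L,        "vit_e_mg",          "MG",
    1095L,        "zinc_mg",           "MG",
    1166L,        "riboflavin_mg",     "MG"
  )
}

default_category_map <- function() {
  list(pb_milk_alternative = c("plant based milk", "plant-based milk",
                               "plant based milk alternatives"),
       pb_water = c("plant based water", "plant-based water",
                    "plant based waters"))
}

normalize_category <- function(x, category_map = default_category_map()) {
  x <- tolower(trimws(x))
  out <- rep(NA_character_, length(x))
  for (nm in names(category_map)) out[x %in% category_map[[nm]]] <- nm
  out
}

#' Load a FoodData Central style branded-food bundle
#'
#' Reads the three-file CSV dialect of USDA FoodData Central branded foods:
#' a food table (`fdc_id`, `description`), a long-format nutrient table
#' (`fdc_id`, `nutrient_id`, `amount`, optional `unit_name`) and a branded
#' food table (`fdc_id`, `brand_owner`, `branded_food_category`,
#' `ingredients`). Products whose USDA-assigned category matches (case
#' insensitively) one of the configured plant-based milk alternative or
#' plant-based water category strings are kept, in stable input order; all
#' other products are dropped. The nutrient long table is pivoted to the
#' per-100 g vector and units normalized (vitamin D mcg to IU at 40 IU/mcg;
#' vitamin A mcg RAE to IU at the configured factor). An unknown unit for a
#' nutrient raises a warning and the value is treated as missing. A nutrient absent from the table is missing (`NA`),
#' which is distinct from an explicit 0.
#'
#' @param food_table_path,nutrient_table_path,branded_table_path CSV paths.
#' @param category_map Named list mapping `pb_milk_alternative` and
#'   `pb_water` to the category strings that belong to them.
#' @param conversions See [unit_conversions()].
#' @return A product tibble in the canonical column order (see
#'   [load_flat()] for the schema).
#' @export
load_bfpdb <- function(food_table_path, nutrient_table_path, branded_table_path,
                       category_map = default_category_map(),
                       conversions = unit_conversions()) {
  food <- read_csv_required(food_table_path, c("fdc_id", "description"))
  nutr <- read_csv_required(nutrient_table_path, c("fdc_id", "nutrient_id", "amount"))
  brand <- read_csv_required(branded_table_path,
                             c("fdc_id", "branded_food_category", "ingredients"))

  base <- dplyr::left_join(food, brand, by = "fdc_id")
  base$usda_category <- normalize_category(base$branded_food_category, category_map)
  base <- base[!is.na(base$usda_category), , drop = FALSE]

  map <- fdc_nutrient_map()
  nutr <- nutr[nutr$fdc_id %in% base$fdc_id, , drop = FALSE]
  nutr <- dplyr::inner_join(nutr, map, by = "nutrient_id",
                            relationship = "many-to-many")
  if ("unit_name" %in% names(nutr)) {
    bad <- !is.na(nutr$unit_name) & toupper(nutr$unit_name) != nutr$unit
    if (any(bad)) {
      warning(sprintf("%d nutrient rows with unrecognized units treated as missing",
                      sum(bad)), call. = FALSE)
      nutr <- nutr[!bad, , drop = FALSE]
    }
  }
  # unit normalization
  nutr$amount <- dplyr::case_when(
    nutr$nutrient_id == 1106L ~ nutr$amount * conversions$vit_a_mcg_rae_to_iu,
    nutr$nutrient_id == 1114L ~ nutr$amount * conversions$vit_d_mcg_to_iu,
    TRUE ~ nutr$amount
  )
  wide <- tidyr::pivot_wider(
    nutr[, c("fdc_id", "column", "amount")],
    names_from = "column", values_from = "amount",
    values_fn = function(x) x[1]
  )

  out <- tibble::tibble(
    product_id = as.character(base$fdc_id),
    long_name = as.character(base$description),
    brand = as.character(base[["brand_owner"]] %||% NA_character_),
    usda_category = base$usda_category,
    fdc_id = base$fdc_id
  )
  out <- dplyr::left_join(out, wide, by = c(fdc_id = "fdc_id"))
  out$fdc_id <- NULL
  for (col in nutrient_columns()) {
    if (!col %in% names(out)) out[[col]] <- NA_real_
  }
  out$ingredients_text <- as.character(base$ingredients)
  out$ingredients_text[is.na(out$ingredients_text)] <- ""
  validate_products(out[, product_columns()])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_csv_required <- function(path, required) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing required column(s): %s",
                 basename(path), paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Load products from a flat wide CSV
#'
#' Entry point for fixtures and synthetic cohorts: one row per product, one
#' column per field of the canonical schema (`product_id`, `long_name`,
#' `brand`, `usda_category`, the per-100 g nutrient columns, and
#' `ingredients_text`). Blank nutrient cells stay missing (`NA`); exclusion
#' of products with missing energy happens later, in the curation stage.
#'
#' @param csv_path Path to the wide CSV.
#' @return A product tibble in canonical column order.
#' @export
load_flat <- function(csv_path) {
  df <- read_csv_required(csv_path, product_columns())
  df <- df[, product_columns()]
  df$product_id <- as.character(df$product_id)
  df$long_name <- as.character(df$long_name)
  df$brand <- as.character(df$brand)
  for (col in nutrient_columns()) df[[col]] <- as.numeric(df[[col]])
  df$ingredients_text <- as.character(df$ingredients_text)
  df$ingredients_text[is.na(df$ingredients_text)] <- ""
  validate_products(tibble::as_tibble(df))
}

validate_products <- function(products) {
  for (col in nutrient_columns()) {
    v <- products[[col]]
    if (any(!is.na(v) & v < 0)) {
      stop(sprintf("negative values in %s violate the product invariants", col),
           call. = FALSE)
    }
  }
  e <- products$energy_kcal_100g
  if (any(!is.na(e) & !is.finite(e))) stop("non-finite energy values", call. = FALSE)
  bad_cat <- !products$usda_category %in% c("pb_milk_alternative", "pb_water")
  if (any(bad_cat)) {
    stop("usda_category must be pb_milk_alternative or pb_water", call. = FALSE)
  }
  products
}

#' Write the combined per-product results table
#'
#' Joins the aligned product, flag, score and standards tables into one wide
#' CSV, one row per product, in a fixed documented column order: the product
#' schema columns first, then ingredient flags, then scores, then standards
#' verdicts. Inputs must cover identical product ids.
#'
#' @param products Product tibble.
#' @param flags Output of [detect_flags()] (may include `plant_source`).
#' @param scores Output of [score_products()].
#' @param standards Output of [check_standards()], or `NULL` for
#'   waters-only runs.
#' @param out_path Destination CSV path.
#' @return Invisibly, the written tibble.
#' @export
write_results <- function(products, flags, scores, standards, out_path) {
  check_aligned <- function(tbl, nm) {
    if (is.null(tbl)) return(invisible())
    if (!identical(sort(tbl$product_id), sort(products$product_id))) {
      stop(sprintf("%s not aligned with products (product_id mismatch)", nm),
           call. = FALSE)
    }
  }
  check_aligned(flags, "flags")
  check_aligned(scores, "scores")
  out <- products |>
    dplyr::left_join(flags, by = "product_id") |>
    dplyr::left_join(scores, by = "product_id")
  if (!is.null(standards)) {
    out <- dplyr::left_join(
      out,
      dplyr::rename_with(standards, ~ paste0("std_", .x), -"product_id"),
      by = "product_id"
    )
  }
  readr::write_csv(out, out_path, na = "")
  invisible(out)
}
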