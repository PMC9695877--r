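#' Proposed per-100 g nutrient standards for PB milk alternatives
#'
#' Threshold configuration for the proposed nutrient standards: maximum
#' energy (85 kcal/100 g for children 4-12 y, 100 for adults >12 y), minimum
#' protein (>2.2 g/100 g; best-of-class >2.8), maximum total sugars (<5.3 /
#' <6.25 g/100 g by population; best-of-class <2.7 / <3.1), maximum saturated
#' fat (<0.75 g/100 g), maximum sodium (<120 mg/100 g), and a micronutrient
#' floor of at least 15% of the daily value per 200 g serving for calcium,
#' riboflavin, vitamin D, vitamin B12 and vitamin A. Protein quality
#' (PDCAAS) is part of the published standard but branded-food label data
#' carry no per-product value, so it is reported as `not_assessed`.
#'
#' The composite verdict follows the operative definition used for the
#' headline pass count: energy, protein, saturated fat, total sugars,
#' calcium, vitamin A and vitamin D (sodium and the B vitamins are listed in
#' the standard but excluded from the composite; both memberships are
#' configurable). The best-of-class verdict is the stricter protein and
#' sugars thresholds only.
#'
#' @param population `"adults_over_12"` (default) or `"children_4_12"`.
#' @param composite_criteria Criteria whose conjunction defines `composite`.
#' @param best_criteria Criteria defining `best_of_class`.
#' @param dv Named daily values for the micronutrient rule.
#' @return A `standards_config` list of thresholds.
#' @export
standards_config <- function(population = c("adults_over_12", "children_4_12"),
                             composite_criteria = c("energy", "protein", "satfat",
                                                    "sugars", "calcium",
                                                    "vitamin_a", "vitamin_d"),
                             best_criteria = c("protein_best", "sugars_best"),
                             dv = c(calcium_mg = 1300, vit_d_iu = 800,
                                    vit_b12_mcg = 2.4, vit_a_iu = 2666,
                                    riboflavin_mg = 1.3)) {
  population <- match.arg(population)
  child <- population == "children_4_12"
  cfg <- list(
    population = population,
    energy_max = if (child) 85 else 100,
    protein_min = 2.2,
    protein_best = 2.8,
    sugars_max = if (child) 5.3 else 6.25,
    sugars_best = if (child) 2.7 else 3.1,
    satfat_max = 0.75,
    sodium_max = 120,
    micronutrient_frac = 0.15,   # of DV per 200 g serving
    serving_g = 200,
    dv = dv,
    composite_criteria = composite_criteria,
    best_criteria = best_criteria
  )
  stopifnot(all(unlist(cfg[c("energy_max", "protein_min", "protein_best",
                             "sugars_max", "sugars_best", "satfat_max",
                             "sodium_max")]) > 0), all(dv > 0))
  class(cfg) <- "standards_config"
  cfg
}

#' Check PB milk alternatives against the proposed nutrient standards
#'
#' Evaluates every per-criterion verdict with the printed inequality
#' directions: maxima are strict `<`, minima strict `>`. The micronutrient
#' floor of 15% DV per 200 g serving translates to per-100 g values of at
#' least `0.15 * DV / 2`, evaluated with `>=` (the floor itself qualifies).
#' `composite` is the conjunction of the configured composite criteria and
#' `best_of_class` of the configured best-of-class criteria. Standards are
#' defined for milk alternatives only; a PB water row is an error.
#'
#' @param products Post-imputation product tibble, category
#'   `pb_milk_alternative`.
#' @param config A [standards_config()].
#' @return Tibble: `product_id`, one logical column per criterion (`energy`,
#'   `protein`, `protein_best`, `sugars`, `sugars_best`, `satfat`, `sodium`,
#'   `calcium`, `vitamin_a`, `vitamin_d`, `riboflavin`, `b12`), `pdcaas`
#'   (always `"not_assessed"`), `composite`, `best_of_class`.
#' @export
check_standards <- function(products, config = standards_config()) {
  if (any(products$usda_category != "pb_milk_alternative")) {
    stop("nutrient standards are defined for PB milk alternatives only",
         call. = FALSE)
  }
  micro <- function(col) {
    floor_100g <- config$micronutrient_frac * config$dv[[col]] /
      (config$serving_g / 100)
    products[[col]] >= floor_100g
  }
  res <- tibble::tibble(
    product_id = products$product_id,
    energy = products$energy_kcal_100g < config$energy_max,
    protein = products$protein_g > config$protein_min,
    protein_best = products$protein_g > config$protein_best,
    sugars = products$total_sugars_g < config$sugars_max,
    sugars_best = products$total_sugars_g < config$sugars_best,
    satfat = products$satfat_g < config$satfat_max,
    sodium = products$sodium_mg < config$sodium_max,
    calcium = micro("calcium_mg"),
    vitamin_a = micro("vit_a_iu"),
    vitamin_d = micro("vit_d_iu"),
    riboflavin = micro("riboflavin_mg"),
    b12 = micro("vit_b12_mcg"),
    pdcaas = "not_assessed"
  )
  conj <- function(criteria) {
    Reduce(`&`, lapply(criteria, function(cr) res[[cr]]))
  }
  res$composite <- conj(config$composite_criteria)
  res$best_of_class <- conj(config$best_criteria)
  res
}

#' Pass rates by group
#'
#' Counts and percentages of products meeting each standards criterion (and
#' the composite and best-of-class verdicts), per group and overall.
#' Percentages are count/denominator x 100, rounded to one decimal. An empty
#' group yields `n = 0` and `NA` percentages.
#'
#' @param results Output of [check_standards()].
#' @param grouping Character vector (one label per result row, e.g. plant
#'   source), or `NULL` for overall rates only.
#' @return Long tibble: `group`, `criterion`, `n`, `n_pass`, `pct_pass`;
#'   `group == "All"` is the overall row. Per-source counts sum to the
#'   overall count for every criterion.
#' @export
pass_rates <- function(results, grouping = NULL) {
  crit_cols <- setdiff(names(results), c("product_id", "pdcaas"))
  one_group <- function(label, idx) {
    purrr::map_dfr(crit_cols, function(cr) {
      v <- results[[cr]][idx]
      tibble::tibble(
        group = label, criterion = cr, n = length(v),
        n_pass = sum(v, na.rm = TRUE),
        pct_pass = if (length(v) > 0L) round(100 * sum(v, na.rm = TRUE) / length(v), 1)
        else NA_real_
      )
    })
  }
  out <- one_group("All", seq_len(nrow(results)))
  if (!is.null(grouping)) {
    stopifnot(length(grouping) == nrow(results))
    for (g in unique(grouping)) {
      out <- dplyr::bind_rows(out, one_group(g, which(grouping == g)))
    }
  }
  out
}
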