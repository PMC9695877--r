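#' Daily-value reference amounts for the NRF5.3 index
#'
#' Reference daily values used by [nrf53()]: five qualifying nutrients
#' (protein 50 g, vitamin A 2666 IU, vitamin D 800 IU, calcium 1300 mg,
#' vitamin B12 2.4 mcg) and three limiting nutrients (saturated fat 20 g,
#' total sugars 90 g, sodium 2300 mg), with each percent-DV capped at 100.
#'
#' @return A list with `qualifying` and `limiting` named numeric vectors
#'   (names are product-table columns) and the `cap`.
#' @export
nrf_reference <- function() {
  list(
    qualifying = c(protein_g = 50, vit_a_iu = 2666, vit_d_iu = 800,
                   calcium_mg = 1300, vit_b12_mcg = 2.4),
    limiting = c(satfat_g = 20, total_sugars_g = 90, sodium_mg = 2300),
    cap = 100
  )
}

#' Nutrient Rich Food index NRF5.3
#'
#' For each product, each nutrient is expressed as a percent of its daily
#' value per 100 kcal of product and capped at 100%; NR5 is the sum over the
#' five qualifying nutrients, LIM the sum over the three limiting nutrients,
#' and NRF5.3 = NR5 - LIM. Beverages with energy density below 10 kcal/100 g
#' are ineligible (to avoid near-zero denominators) and get `NA` scores with
#' `nrf_eligible = FALSE`, never `NaN`.
#'
#' Missing nutrient values are treated as 0 with a warning; score products
#' after imputation.
#'
#' @param products Product tibble (post-imputation).
#' @param reference See [nrf_reference()].
#' @return Tibble: `product_id`, `nr5`, `lim`, `nrf53`, `nrf_eligible`.
#' @export
nrf53 <- function(products, reference = nrf_reference()) {
  energy <- products$energy_kcal_100g
  eligible <- !is.na(energy) & energy >= 10
  cols <- c(names(reference$qualifying), names(reference$limiting))
  vals <- as.matrix(products[, cols])
  if (anyNA(vals)) {
    warning("missing nutrient values treated as 0 in NRF5.3; impute first",
            call. = FALSE)
    vals[is.na(vals)] <- 0
  }
  pct <- function(col, dv) {
    p <- (vals[, col] * 100 / energy) / dv * 100
    pmin(p, reference$cap)
  }
  sum_pct <- function(ref) {
    m <- vapply(names(ref), function(cl) pct(cl, ref[[cl]]),
                numeric(nrow(products)))
    if (is.null(dim(m))) m <- matrix(m, nrow = nrow(products))
    rowSums(m)
  }
  nr5 <- sum_pct(reference$qualifying)
  lim <- sum_pct(reference$limiting)
  tibble::tibble(
    product_id = products$product_id,
    nr5 = ifelse(eligible, nr5, NA_real_),
    lim = ifelse(eligible, lim, NA_real_),
    nrf53 = ifelse(eligible, nr5 - lim, NA_real_),
    nrf_eligible = eligible
  )
}

# 2017 Nutri-Score component point tables. Each vector holds the thresholds:
# points = number of thresholds strictly exceeded.
ns_tables <- function(mode) {
  solid <- list(
    energy_kj = 335 * (1:10),
    sugars_g = c(4.5, 9, 13.5, 18, 22.5, 27, 31, 36, 40, 45),
    satfat_g = 1:10,
    sodium_mg = 90 * (1:10),
    fiber_g = c(0.9, 1.9, 2.8, 3.7, 4.7),
    protein_g = c(1.6, 3.2, 4.8, 6.4, 8.0),
    fvln_pct = c(40, 60, 80),
    fvln_points = c(0, 1, 2, 5)
  )
  if (mode == "solid") return(solid)
  # Beverages: stricter energy and sugar scales, anchored at >30 kJ and
  # >1.5 g/100 g with uniform steps; fvln doubled.
  bev <- solid
  bev$energy_kj <- 30 * (1:10)
  bev$sugars_g <- 1.5 * (1:10)
  bev$fvln_points <- c(0, 2, 4, 10)
  bev
}

points_from_thresholds <- function(x, thresholds) {
  vapply(x, function(v) sum(v > thresholds), numeric(1))
}

#' Nutri-Score points and grade
#'
#' Computes the 2017 Nutri-Score point algorithm in either its solid-food or
#' its beverage mode; the point of scoring the same beverage both ways is
#' that current rules require plant-based beverages to be scored as solid
#' foods, while the beverage tables are far stricter. Negative "A" points
#' come from energy (kJ), saturated fat, total sugars and sodium; positive
#' "C" points from protein, fiber and the fruit/vegetable/legume/nut content.
#' The first solid thresholds are >335 kJ/100 g energy and >4.5 g/100 g
#' sugars; the first beverage thresholds are >30 kJ/100 g and >1.5 g/100 g.
#' When A points reach 11 and the product is not predominantly (>80% by
#' weight) fruit/vegetable/legume/nut, protein points are excluded and the
#' final score is A points minus fiber (and fvln) points only.
#'
#' Energy is taken from `energy_kcal_100g` and converted at 4.184 kJ/kcal.
#' `fvln_pct` defaults to 0 because branded-food label data do not carry it;
#' it can be overridden per product.
#'
#' @param products Product tibble (post-imputation; negative nutrient values
#'   are an error, missing fiber is treated as 0 with a warning).
#' @param mode `"solid"` or `"beverage"`.
#' @param fvln_pct Fruit/vegetable/legume/nut percent by weight, length 1 or
#'   one per product.
#' @param is_water Logical, length 1 or per product: plain water, which is
#'   the only beverage awarded grade A in beverage mode.
#' @return Tibble: `product_id`, `mode`, `a_points`, `c_points`,
#'   `final_points`, `grade`.
#' @export
nutriscore <- function(products, mode = c("solid", "beverage"),
                       fvln_pct = 0, is_water = FALSE) {
  mode <- match.arg(mode)
  n <- nrow(products)
  fvln_pct <- rep_len(fvln_pct, n)
  is_water <- rep_len(is_water, n)
  tab <- ns_tables(mode)

  need <- c("energy_kcal_100g", "satfat_g", "total_sugars_g", "sodium_mg",
            "protein_g")
  for (col in need) {
    v <- products[[col]]
    if (any(!is.na(v) & v < 0)) stop("negative ", col, " in Nutri-Score input",
                                     call. = FALSE)
    if (anyNA(v)) stop("missing ", col, " in Nutri-Score input", call. = FALSE)
  }
  fiber <- products$fiber_g
  if (anyNA(fiber)) {
    warning("missing fiber treated as 0 in Nutri-Score", call. = FALSE)
    fiber[is.na(fiber)] <- 0
  }

  energy_kj <- products$energy_kcal_100g * unit_conversions()$kcal_to_kj
  a_points <- points_from_thresholds(energy_kj, tab$energy_kj) +
    points_from_thresholds(products$total_sugars_g, tab$sugars_g) +
    points_from_thresholds(products$satfat_g, tab$satfat_g) +
    points_from_thresholds(products$sodium_mg, tab$sodium_mg)
  protein_pts <- points_from_thresholds(products$protein_g, tab$protein_g)
  fiber_pts <- points_from_thresholds(fiber, tab$fiber_g)
  fvln_pts <- tab$fvln_points[points_from_thresholds(fvln_pct, tab$fvln_pct) + 1L]
  fvln_max <- fvln_pct > 80

  c_points <- ifelse(a_points >= 11 & !fvln_max,
                     fiber_pts + fvln_pts,
                     protein_pts + fiber_pts + fvln_pts)
  final <- a_points - c_points
  grade <- nutriscore_grade(final, mode, is_water)
  tibble::tibble(
    product_id = products$product_id,
    mode = mode,
    a_points = as.integer(a_points),
    c_points = as.integer(c_points),
    final_points = as.integer(final),
    grade = grade
  )
}

#' Convert Nutri-Score points to a letter grade
#'
#' Solid foods: <= -1 is A, 0-2 B, 3-10 C, 11-18 D, >= 19 E. Beverages:
#' plain water is A; any score <= 1 for a non-water beverage is B, 2-5 C,
#' 6-9 D, >= 10 E. The printed bands leave the points -1/19 (solid) and 10
#' (beverage) unstated; they are closed toward the published convention as
#' above.
#'
#' @param final_points Integer point scores.
#' @param mode `"solid"` or `"beverage"`.
#' @param is_water Logical, recycled.
#' @return Character vector of grades `"A"`-`"E"`.
#' @export
nutriscore_grade <- function(final_points, mode = c("solid", "beverage"),
                             is_water = FALSE) {
  mode <- match.arg(mode)
  is_water <- rep_len(is_water, length(final_points))
  if (mode == "solid") {
    dplyr::case_when(
      final_points <= -1 ~ "A",
      final_points <= 2 ~ "B",
      final_points <= 10 ~ "C",
      final_points <= 18 ~ "D",
      TRUE ~ "E"
    )
  } else {
    dplyr::case_when(
      is_water ~ "A",
      final_points <= 1 ~ "B",
      final_points <= 5 ~ "C",
      final_points <= 9 ~ "D",
      TRUE ~ "E"
    )
  }
}

#' Choices International beverage criteria
#'
#' The Choices International scheme for non-dairy milk alternatives: a
#' product passes only if all four criteria hold (strict inequalities):
#' saturated fat < 1.1 g/100 g, sodium < 100 mg/100 g, total sugars
#' < 5.0 g/100 g, and energy < 40 kcal/100 g.
#'
#' @param products Product tibble (post-imputation, complete nutrient vector).
#' @return Tibble: `product_id`, `choices_pass`, and `choices_failed`
#'   (semicolon-joined subset of `satfat;sodium;sugars;energy`, empty iff
#'   passing).
#' @export
choices <- function(products) {
  fails <- cbind(
    satfat = !(products$satfat_g < 1.1),
    sodium = !(products$sodium_mg < 100),
    sugars = !(products$total_sugars_g < 5.0),
    energy = !(products$energy_kcal_100g < 40)
  )
  failed <- apply(fails, 1L, function(r) paste(colnames(fails)[r], collapse = ";"))
  tibble::tibble(
    product_id = products$product_id,
    choices_pass = rowSums(fails) == 0L,
    choices_failed = failed
  )
}

#' Score products with all three nutrient density metrics
#'
#' Convenience wrapper combining [nrf53()], [nutriscore()] in both modes, and
#' [choices()] into one tibble keyed by `product_id`. Nutri-Score columns are
#' prefixed `ns_solid_` / `ns_beverage_`.
#'
#' @inheritParams nutriscore
#' @param reference See [nrf_reference()].
#' @return One wide tibble per product with all score columns.
#' @export
score_products <- function(products, reference = nrf_reference(),
                           fvln_pct = 0, is_water = FALSE) {
  ns_wide <- function(mode) {
    ns <- nutriscore(products, mode = mode, fvln_pct = fvln_pct,
                     is_water = is_water)
    ns$mode <- NULL
    dplyr::rename_with(ns, ~ paste0("ns_", mode, "_", .x), -"product_id")
  }
  nrf53(products, reference) |>
    dplyr::left_join(ns_wide("solid"), by = "product_id") |>
    dplyr::left_join(ns_wide("beverage"), by = "product_id") |>
    dplyr::left_join(choices(products), by = "product_id")
}
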