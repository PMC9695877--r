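# Independent spreadsheet-style NRF5.3 oracle: plain arithmetic, no shared
# code with the implementation.
nrf_oracle <- function(p) {
  dv <- c(protein_g = 50, vit_a_iu = 2666, vit_d_iu = 800, calcium_mg = 1300,
          vit_b12_mcg = 2.4)
  lim_ref <- c(satfat_g = 20, total_sugars_g = 90, sodium_mg = 2300)
  per100kcal <- function(col) p[[col]] * 100 / p$energy_kcal_100g
  nr5 <- 0
  for (col in names(dv)) nr5 <- nr5 + min(100, per100kcal(col) / dv[[col]] * 100)
  lim <- 0
  for (col in names(lim_ref)) lim <- lim + min(100, per100kcal(col) / lim_ref[[col]] * 100)
  c(nr5 = nr5, lim = lim, nrf53 = nr5 - lim)
}

test_that("NRF5.3 matches the hand-worked example", {
  p <- make_product(energy_kcal_100g = 50, protein_g = 2.5, calcium_mg = 120,
                    vit_d_iu = 40, vit_a_iu = 150, vit_b12_mcg = 0.5,
                    satfat_g = 0.2, total_sugars_g = 2, sodium_mg = 50)
  got <- nrf53(p)
  # 10 + 18.46 + 10 + 11.25 + 41.67 and 2 + 4.44 + 4.35, computed exactly
  expect_equal(got$nr5, 10 + 240 / 13 + 10 + 30000 / 2666 + 125 / 3,
               tolerance = 1e-9)
  expect_equal(got$lim, 2 + 40 / 9 + 100 / 23, tolerance = 1e-9)
  expect_equal(got$nrf53, got$nr5 - got$lim, tolerance = 1e-12)
})

test_that("NRF5.3 zero vector, cap and eligibility behave as specified", {
  zero <- make_product(energy_kcal_100g = 100, protein_g = 0, calcium_mg = 0,
                       vit_d_iu = 0, vit_a_iu = 0, vit_b12_mcg = 0,
                       satfat_g = 0, total_sugars_g = 0, sodium_mg = 0)
  expect_equal(nrf53(zero)$nrf53, 0)

  # absurd protein is capped at 100 %DV
  capped <- make_product(energy_kcal_100g = 100, protein_g = 200,
                         calcium_mg = 0, vit_d_iu = 0, vit_a_iu = 0,
                         vit_b12_mcg = 0, satfat_g = 0, total_sugars_g = 0,
                         sodium_mg = 0)
  expect_equal(nrf53(capped)$nr5, 100)

  # below 10 kcal/100 g: explicit ineligible marker, never NaN
  low <- make_product(energy_kcal_100g = 9.9)
  got <- nrf53(low)
  expect_false(got$nrf_eligible)
  expect_true(is.na(got$nrf53) && !is.nan(got$nrf53))
  expect_true(nrf53(make_product(energy_kcal_100g = 10))$nrf_eligible)
})

test_that("NRF5.3 equals the independent oracle on random nutrient vectors", {
  set.seed(401)
  for (i in 1:50) {
    p <- make_product(
      energy_kcal_100g = runif(1, 10, 250),
      protein_g = runif(1, 0, 12), calcium_mg = runif(1, 0, 400),
      vit_d_iu = runif(1, 0, 200), vit_a_iu = runif(1, 0, 800),
      vit_b12_mcg = runif(1, 0, 3), satfat_g = runif(1, 0, 10),
      total_sugars_g = runif(1, 0, 15), sodium_mg = runif(1, 0, 300)
    )
    expected <- nrf_oracle(p)
    got <- nrf53(p)
    expect_equal(got$nr5, unname(expected["nr5"]), tolerance = 1e-9)
    expect_equal(got$lim, unname(expected["lim"]), tolerance = 1e-9)
    expect_equal(got$nrf53, unname(expected["nrf53"]), tolerance = 1e-9)
  }
})

test_that("NRF5.3 is monotone in qualifying and limiting nutrients below the cap", {
  base <- make_product(energy_kcal_100g = 60)
  up <- function(col, delta) {
    p <- base
    p[[col]] <- p[[col]] + delta
    p
  }
  for (col in c("protein_g", "calcium_mg", "vit_d_iu", "vit_a_iu", "vit_b12_mcg")) {
    expect_gt(nrf53(up(col, 0.1))$nrf53, nrf53(base)$nrf53)
  }
  for (col in c("satfat_g", "total_sugars_g", "sodium_mg")) {
    expect_lt(nrf53(up(col, 0.1))$nrf53, nrf53(base)$nrf53)
  }
})

test_that("Nutri-Score anchors: water, first thresholds, printed grade bands", {
  water <- make_product(energy_kcal_100g = 0, protein_g = 0, satfat_g = 0,
                        total_sugars_g = 0, sodium_mg = 0, fiber_g = 0,
                        usda_category = "pb_water")
  expect_equal(nutriscore(water, "beverage", is_water = TRUE)$grade, "A")

  # 80 kJ/100 g is above the 30 kJ beverage first threshold
  p80 <- make_product(energy_kcal_100g = 80 / 4.184, protein_g = 0,
                      satfat_g = 0, total_sugars_g = 0, sodium_mg = 0,
                      fiber_g = 0)
  ns <- nutriscore(p80, "beverage")
  expect_gte(ns$a_points, 1L)
  expect_equal(ns$grade, nutriscore_grade(ns$final_points, "beverage"))
  # ... but below the 335 kJ solid first threshold
  expect_equal(nutriscore(p80, "solid")$a_points, 0L)

  expect_equal(nutriscore_grade(12L, "solid"), "D")
  expect_equal(nutriscore_grade(7L, "beverage"), "D")
  expect_equal(nutriscore_grade(-1L, "beverage", is_water = FALSE), "B")
  # band-gap closures
  expect_equal(nutriscore_grade(-1L, "solid"), "A")
  expect_equal(nutriscore_grade(19L, "solid"), "E")
  expect_equal(nutriscore_grade(10L, "beverage"), "E")
})

test_that("Nutri-Score grades are non-decreasing in points and A-components monotone", {
  pts <- -5:25
  g_solid <- nutriscore_grade(pts, "solid")
  g_bev <- nutriscore_grade(pts, "beverage")
  expect_true(all(diff(match(g_solid, LETTERS)) >= 0))
  expect_true(all(diff(match(g_bev, LETTERS)) >= 0))

  base <- make_product(energy_kcal_100g = 50, total_sugars_g = 3,
                       satfat_g = 1, sodium_mg = 100, protein_g = 0,
                       fiber_g = 0)
  for (col in c("energy_kcal_100g", "total_sugars_g", "satfat_g", "sodium_mg")) {
    for (mode in c("solid", "beverage")) {
      lo <- nutriscore(base, mode)$a_points
      hi_p <- base
      hi_p[[col]] <- hi_p[[col]] * 20
      expect_gte(nutriscore(hi_p, mode)$a_points, lo)
    }
  }
})

test_that("protein points are excluded when A points reach 11 without the fvln criterion", {
  rich <- make_product(energy_kcal_100g = 200, total_sugars_g = 20,
                       satfat_g = 5, sodium_mg = 400, protein_g = 9,
                       fiber_g = 5)
  ns <- nutriscore(rich, "solid")
  expect_gte(ns$a_points, 11L)
  expect_equal(ns$c_points, 5L)  # fiber only (5 points), protein (5) dropped
  # with > 80% fruit/vegetable/legume/nut content protein counts again
  ns_fvln <- nutriscore(rich, "solid", fvln_pct = 85)
  expect_equal(ns_fvln$c_points, 5L + 5L + 5L)
})

test_that("the same product scores better (lower) as a solid than as a beverage", {
  cohort <- generate_cohort(synthetic_config("milk", seed = 42))
  solid <- nutriscore(cohort, "solid")
  bev <- nutriscore(cohort, "beverage")
  expect_lt(mean(solid$final_points), mean(bev$final_points))
  # per-product, beverage scoring is never more favorable
  expect_true(all(solid$final_points <= bev$final_points))
})

test_that("Choices anchors: published almond means pass, coconut means fail on sat fat", {
  almond <- category_mean_product("almond")
  got <- choices(almond)
  expect_true(got$choices_pass)
  expect_equal(got$choices_failed, "")

  coconut <- category_mean_product("coconut")
  got <- choices(coconut)
  expect_false(got$choices_pass)
  expect_match(got$choices_failed, "satfat")
})

test_that("Choices boundaries are strict inequalities", {
  boundary <- make_product(energy_kcal_100g = 40, satfat_g = 0, sodium_mg = 0,
                           total_sugars_g = 0)
  expect_false(choices(boundary)$choices_pass)
  expect_equal(choices(boundary)$choices_failed, "energy")
  under <- make_product(energy_kcal_100g = 39.9, satfat_g = 1.09,
                        sodium_mg = 99.9, total_sugars_g = 4.99)
  expect_true(choices(under)$choices_pass)
})

test_that("score_products combines all metrics keyed by product", {
  p <- make_product(product_id = c("a", "b"), energy_kcal_100g = c(50, 5))
  got <- score_products(p)
  expect_equal(got$product_id, c("a", "b"))
  expect_true(all(c("nrf53", "ns_solid_final_points", "ns_beverage_final_points",
                    "ns_solid_grade", "ns_beverage_grade", "choices_pass")
                  %in% names(got)))
  expect_false(got$nrf_eligible[2])
})
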