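# nutridense

Nutrient profiling of plant-based (PB) milk alternatives and PB waters from
branded-food label data.

PB milk alternatives (almond, soy, oat, coconut, pea, ...) are marketed as
substitutes for dairy milk, but their protein, sugar, fat and fortification
profiles vary enormously by plant base and brand. `nutridense` is an R
package for analysts and product developers who want to audit that
variation from label data alone. It reads USDA FoodData Central style
branded-food tables (or any flat CSV of per-100 g nutrient panels plus
ingredient statements), mines the ingredient lists for added sugars, added
sodium and fortificants, classifies each beverage by its first-listed plant
source, imputes undeclared vitamin values from category medians, checks
milk alternatives against proposed per-100 g nutrient standards, and scores
every product with three established nutrient density metrics:

* **NRF5.3** — the Nutrient Rich Food index,
  `NRF5.3 = NR5 − LIM`, where NR5 sums the capped %DV per 100 kcal of five
  qualifying nutrients (protein, vitamin A, vitamin D, calcium, vitamin
  B12) and LIM sums three limiting ones (saturated fat, total sugars,
  sodium). Products under 10 kcal/100 g are flagged ineligible.
* **Nutri-Score (2017), both modes** — the A-points-minus-C-points
  front-of-pack algorithm, computed with the solid-food tables *and* the
  far stricter beverage tables, because current rules require PB beverages
  to be graded as solid foods and the gap between the two verdicts is
  itself informative.
* **Choices International** — pass iff saturated fat < 1.1 g, sodium
  < 100 mg, total sugars < 5.0 g and energy < 40 kcal per 100 g.

A synthetic cohort generator calibrated to published category-level means
and SEs (13 milk categories, n = 1042; 5 water categories, n = 550) makes
the whole pipeline testable without downloading the database. See the
methods vignette (`vignettes/nutrient-profiling-methods.Rmd`) for the
models, assumptions and design decisions.

## Worked example

Score a synthetic cohort generated at the published category parameters and
run the full pipeline:

```r
library(nutridense)

cohort <- generate_cohort(synthetic_config("milk", seed = 1))
res <- run_pipeline(products = cohort)

s <- res$score_summary
s[s$variable == "nrf53", c("group", "n", "mean", "se")][1:6, ]
#>       group    n mean    se
#> 1       All 1042 43.4  1.83
#> 2    almond  407 78.2  2.81
#> 3 macadamia   15 75.8 10.28
#> 4       pea   23 75.1  6.74
#> 5    walnut    8 70.1 12.84
#> 6    quinoa    3 58.3 28.07
```

Mean NRF5.3 is highest for the almond, macadamia and pea categories — the
well-fortified, low-energy bases — and the "All" row is dragged down by
coconut milks (high saturated fat, low fortification). Standards pass
rates for the milk alternatives:

```r
pr <- res$pass_rates
pr[pr$group == "All" & pr$criterion %in%
     c("protein", "sugars", "satfat", "composite", "best_of_class"), ]
#>   group     criterion    n n_pass pct_pass
#> 1   All       protein 1042    195     18.7
#> 2   All        sugars 1042    926     88.9
#> 3   All        satfat 1042    770     73.9
#> 4   All     composite 1042      0      0.0
#> 5   All best_of_class 1042     69      6.6
```

Protein is the limiting nutrient: fewer than one in five products clears
the 2.2 g/100 g minimum, while the sugar and saturated-fat ceilings are
easy to meet. (The composite row also requires the micronutrient
fortification floors, which the generator's single moderate
fortified-amount distribution rarely clears — see the vignette's
limitations section.) And the two Nutri-Score modes disagree sharply on
the same products:

```r
tt <- res$score_tests$paired_t_solid_minus_beverage
sprintf("paired t (solid - beverage) = %.1f on %d pairs", tt$t, tt$df + 1)
#> [1] "paired t (solid - beverage) = -76.0 on 1042 pairs"

res$score_tests$spearman_nsbev_nrf$rho
#> [1] -0.72
```

Solid-food scoring is systematically more favorable than beverage scoring
(negative t), and beverage-mode Nutri-Score points correlate negatively
with NRF5.3 (lower points are better in Nutri-Score, higher is better in
NRF).

To analyze a real branded-food snapshot instead, point `load_bfpdb()` at
the `food.csv` / `food_nutrient.csv` / `branded_food.csv` bundle and pass
the result to `run_pipeline(products = ...)`.

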