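---
title: "Nutrient profiling of plant-based beverages: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nutrient profiling of plant-based beverages: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutridense)
```

## The problem

Plant-based (PB) milk alternatives — almond, soy, oat, coconut, pea and a
dozen smaller categories — are marketed as substitutes for dairy milk, but
their nutrient content varies enormously by plant base and brand. PB waters
(coconut, aloe, birch/maple sap, fruit) are a second growing category
positioned against sugar-sweetened beverages. `nutridense` implements a
reproducible label-data pipeline for both: read branded-food records
(per-100 g nutrient panels plus verbatim ingredient statements), mine the
ingredient lists, impute undeclared vitamins, score each product with three
established nutrient density metrics, and check milk alternatives against
proposed per-100 g nutrient standards.

The pipeline stages, in order:

1. **Load** (`load_bfpdb()`, `load_flat()`) — three-file FoodData Central
   dialect or a flat wide CSV; units normalized (vitamin D 40 IU/mcg;
   vitamin A at a configurable 3.33 IU/mcg RAE, the retinyl-ester
   assumption matching "vitamin A palmitate" on labels). A nutrient absent
   from the data is *missing*, which is distinct from an explicit 0; the
   distinction drives imputation.
2. **Lexicon** (`tokenize_ingredients()`, `detect_flags()`,
   `classify_plant_source()`) — US labels list ingredients in decreasing
   order of amount ("order of predominance"), which makes the ingredient
   statement a ranked signal, not a bag of words.
3. **Curation** (`apply_exclusions()`, `compute_medians()`,
   `impute_vitamins()`).
4. **Scoring** (`nrf53()`, `nutriscore()`, `choices()`).
5. **Standards** (`check_standards()`, `pass_rates()`) and **summaries**
   (`summarize_groups()`, `anova_oneway()`, `spearman_cor()`, `paired_t()`).

`run_pipeline()` wires the stages together and can materialize every
intermediate table for auditing.

## Ingredient mining

`tokenize_ingredients()` splits on top-level commas, flattening
parenthetical sub-ingredients into the stream immediately after their host
phrase, so predominance order is preserved:

```{r}
tokenize_ingredients(
  "Flax milk (filtered water, cold pressed flax oil), pea protein isolate, cane sugar")
```

Term matching is case-insensitive, word-boundary based substring search
within each token, with an optional plural "s". This was chosen over
exact-phrase equality because labels embed qualifiers ("organic cane
sugar", "pure cane sugar") — and over unanchored substring search because
of classic false hits: "pea" must not fire inside "peanut", "oat" not
inside "goats", "salt" not inside "sunflower lecithin". Multi-word terms
are tried longest-first during plant-source classification for the same
reason.

Decisions that were genuinely open:

* **Bare "sodium" counts as added sodium** even inside the sodium salt of
  an added nutrient (e.g. "sodium ascorbate"), because label sodium can
  come either as salt or as sodium salts of added nutrients. An exclusion
  list (`sodium_exclude`, default empty) lets a user tighten this.
* **Emulsifiers never classify**: "soy lecithin" and "sunflower lecithin"
  are excluded from plant-source assignment — otherwise a large share of
  almond milks would classify as soy or seeds. The exclusion list is
  configurable, so the behavior can be disabled.
* **Vitamin D and E term lists** include the label spellings "vitamin D2"/
  "vitamin D3" and "vitamin E" alongside the chemical names
  (ergocalciferol, cholecalciferol, tocopherol): real labels use both
  interchangeably, and the worked label examples require it.
* **Plant-source rule**: the product name decides only when it names
  exactly one plant family; otherwise the first plant term in predominance
  order decides (this also resolves blends and names like "golden milk"
  that carry no plant hint). Flax and hemp collapse to `flax_hemp`,
  pistachio-type nuts to `tree_nut`, seed and fruit bases to
  `seeds_fruit`; waters classify as coconut/aloe/tree/fruit, with
  `plain_flavored` for water-plus-flavors products. The fruit-name list
  for waters is a best-effort default and editable via `read_lexicon()`.

## Exclusions and vitamin imputation

Products with missing energy density or energy above 250 kcal/100 g (a
value more consistent with solid foods) are excluded; the boundary is
strict, so exactly 250 is kept. Both rules produce machine-readable
reasons.

Vitamins A, D and B12 are frequently fortified but under-reported in label
data. The imputation rule is: a missing value whose fortificant appears on
the ingredient list gets the median declared amount for the product type;
a missing value with no declaration gets 0; declared values are never
touched, and every value carries a provenance tag. Two interpretations
were open and are both configurable:

* **Donor set** — default restricts median donors to *fortified* products
  (fortificant flag true), because unfortified products legitimately sit
  near zero and would drag the median down; `donors = "declared"` uses all
  non-missing values.
* **Product type** — default is the plant-source category (almond, soy,
  ...), not the coarser two-way milk/water split; a category with no
  donors falls back to the global median, and a vitamin with no donors
  anywhere imputes to 0 with a warning.

Imputation is idempotent and touches nothing but the three vitamins.

## The three metrics

### NRF5.3

The Nutrient Rich Food index used here has five qualifying nutrients
(protein, vitamin A, vitamin D, calcium, vitamin B12) and three limiting
ones (saturated fat, total sugars, sodium). Each is expressed as a percent
of its daily value (protein 50 g, vitamin A 2666 IU, vitamin D 800 IU,
calcium 1300 mg, B12 2.4 mcg; sat fat 20 g, sugars 90 g, sodium 2300 mg)
*per 100 kcal* of product, capped at 100%:

$$\mathrm{NRF5.3} = \underbrace{\sum_{i=1}^{5}\min\!\Big(100,\;
\frac{x_i \cdot 100/\mathrm{ED}}{\mathrm{DV}_i}\times 100\Big)}_{NR_5}
\;-\;\underbrace{\sum_{j=1}^{3}\min\!\Big(100,\;
\frac{x_j \cdot 100/\mathrm{ED}}{\mathrm{DV}_j}\times 100\Big)}_{LIM}$$

where ED is energy density in kcal/100 g. The cap is applied *after* the
per-100 kcal transformation, matching the order in which the definition is
stated. Products below 10 kcal/100 g are ineligible (the per-calorie
transform degenerates) and are flagged explicitly rather than returning
`NaN`.

```{r}
p <- tibble::tibble(product_id = "demo", energy_kcal_100g = 50,
                    protein_g = 2.5, calcium_mg = 120, vit_d_iu = 40,
                    vit_a_iu = 150, vit_b12_mcg = 0.5, satfat_g = 0.2,
                    total_sugars_g = 2, sodium_mg = 50)
nrf53(p)
```

### Nutri-Score, twice

Nutri-Score converts nutrient point totals (negative "A" points for
energy, saturated fat, total sugars, sodium; positive "C" points for
protein, fiber and fruit/vegetable/legume/nut content) into A–E grades. The
scheme has distinct point tables and grade bands for solid foods and for
beverages — and current regulations require PB beverages to be scored *as
solid foods*. The package therefore scores every product both ways; the
contrast between the two modes is itself a finding.

Component tables follow the published 2017 algorithm. The solid-food
scales start at >335 kJ/100 g (energy) and >4.5 g/100 g (sugars); sat fat
steps at 1 g and sodium at 90 mg. The beverage energy and sugar scales are
built as uniform steps of 30 kJ and 1.5 g anchored at the published first
thresholds (>30 kJ, >1.5 g), ten steps each — the beverage scales are
stated in the source material only by their first thresholds, so the
uniform-step construction is our documented interpretation. Protein
exclusion: when A points reach 11 and the product is not >80% by weight
fruit/vegetable/legume/nut, protein points are dropped and only fiber (and
fvln) points count.

`fvln_pct` defaults to 0: branded-food label data carry no
fruit/vegetable/legume/nut percentage. The >80% rule is implemented but
inert at the default; a per-product override column is accepted.

Grade bands as printed leave three point values unstated; they are closed
toward the published convention: solid −1 → A (i.e. ≤ −1), solid 19 → E
(≥ 19), beverage 10 → E (≥ 10). For beverages the B band is "minimum to
1", read as any score ≤ 1 for a non-water beverage; only plain water gets
A in beverage mode. Energy is converted at 4.184 kJ/kcal inside the
scorer; kcal is the package-wide canonical unit.

### Choices International

A pure threshold scheme for non-dairy milk alternatives: pass iff
saturated fat < 1.1 g, sodium < 100 mg, total sugars < 5.0 g and energy
< 40 kcal, all per 100 g and all strict inequalities.

## Proposed nutrient standards

`standards_config()` holds the proposed per-100 g standards for PB milk
alternatives: energy < 85 (children 4–12 y) / < 100 (adults) kcal; protein
> 2.2 g with a "best of class" bar at > 2.8 g; total sugars < 5.3 / < 6.25 g
with best-of-class < 2.7 / < 3.1 g; saturated fat < 0.75 g; sodium
< 120 mg; and ≥ 15% DV per 200 g serving for calcium, riboflavin, vitamin
D, vitamin B12 and vitamin A — which translates to 0.15 × DV / 2 per
100 g, evaluated with `>=` (the floor qualifies; the choice of strict vs
non-strict at the exact boundary is immaterial on real-valued data and is
documented here).

Interpretation choices, both configurable:

* **Composite membership** — energy, protein, saturated fat, total
  sugars, calcium, vitamin A, vitamin D. Sodium and the B vitamins are
  listed in the standard but excluded from the composite, following the
  operative definition of the headline pass count.
* **Best of class** — the stricter protein and sugars thresholds only,
  not composite-AND-best.

Sugar standards are evaluated on **total** sugars: added-sugar amounts are
not available in branded label data, so total sugars stand in — a
conservative substitution for unsweetened products and a documented
caveat. The protein-quality (PDCAAS) row of the published standard is
reported as `not_assessed`: no per-product PDCAAS exists in label data.
One source passage prints the best-of-class sugar bar as 3.2 g/100 g where
the operative definition uses 3.1; 3.1 is used.

## Statistics

Group summaries report mean and SE = SD/√n; single-member groups print SE
0.00 (mirroring published table conventions) with an explicit
`se_undefined` flag in machine output. One-way ANOVA uses the classical F
with pairwise Bonferroni-adjusted post hoc t tests (Tukey HSD available);
correlations between score systems are Spearman; the two Nutri-Score modes
are compared with a paired t test, differences taken solid − beverage so a
negative t means solid scoring is more favorable. The significance
threshold used in reporting is p < 0.01. All of these call the standard
`stats` routines; the test suite checks them against hand-coded closed
forms.

## The synthetic cohort generator

There is no redistributable snapshot of the branded-food database, so the
package ships a generator (`generate_cohort()`, `generate_waters()`) whose
defaults emulate the published study cohort: 13 milk-alternative
categories (n = 1042 total) and 5 water categories (n = 550) with the
published per-category means and SEs, ingredient statements assembled in
predominance order, and configurable sweetening/salting/fortification
prevalences.

Distributional choices:

* **Gamma, moment-matched.** Only means and SEs are published, so the
  generator needs a nonnegative family that reproduces them exactly. A
  normal truncated at zero was considered and rejected: truncation shifts
  the realized mean far above the nominal one for near-zero nutrients
  (e.g. almond sat fat, mean 0.06 g with SD = SE × √n ≈ 0.20 g, would
  generate around 0.19 g — three times the published mean). The gamma with
  shape (m/s)² and scale s²/m has exactly the published mean and SD on
  nonnegative support. SD = 0 categories generate constants; mean = 0
  generates zeros.
* **Energy CV.** The energy column is published without an SE; the
  generator assumes a coefficient of variation of 0.25, a round number in
  the range typical of branded-food categories.
* **Prevalences.** Added sugars 0.51 (published cohort rate); fortificant
  prevalences from the published counts out of 1042 (calcium 672 → 0.65,
  vitamin D 648 → 0.60, vitamin A 620 → 0.60, B12 344 → 0.35, vitamin E
  210 → 0.20, zinc 110 → 0.10); salt 0.80 for milks ("most" carry added
  sodium) and 0.20 for waters; vitamin C in 0.25 of waters; vitamin
  missingness 0.15. Per-category sweetening/fortification rates are
  published only as a bar chart and were deliberately not read off the
  figure; the cohort-level defaults are the documented assumption.
* **Fortified amounts.** Fortified products draw vitamin amounts from
  round-number distributions typical of US fortification practice
  (vitamin A 160 ± 40 IU/100 g, vitamin D 42 ± 10 IU, B12 0.63 ± 0.25
  mcg); unfortified products get 0, and the ingredient text always agrees
  with the fortification indicators, so flag recovery is exact by
  construction.
* **Independence.** Within-product correlations between nutrients are not
  modeled; nothing in the published summaries constrains them.

What the generator does *not* reproduce — and therefore what passing
tests do and do not show about real data:

* Real sodium distributions are bounded; the moment-matched gamma for
  coconut water (mean 23.4, SD ≈ 12.3 mg) places about 1.1% of its mass
  above a 60 mg screen that 100% of the real sample cleared. Tests assert
  the distribution-derived bound, not the empirical 100%.
* Fortified-amount heterogeneity is a single distribution per vitamin. In
  real data a subpopulation is fortified heavily enough to clear the 15%
  DV/serving floors (hence a two-digit composite pass rate); under the
  single moderate distribution the micronutrient floors are rarely
  cleared, so synthetic composite pass rates are near zero and synthetic
  mean NRF5.3 runs below the published value. Pass rates for the
  macronutrient criteria, the score orderings between categories, the
  mode contrast between the two Nutri-Scores, and the negative
  Spearman correlation between beverage-mode points and NRF5.3 all
  reproduce.
* Brand names and full real ingredient grammar are out of scope; the
  generated statements are schematic labels.

## Numerical conventions and degenerate inputs

* Strict inequalities everywhere the standards and Choices thresholds are
  printed with `<`/`>`; the 250 kcal exclusion bound and the 15% DV floor
  are the two boundaries where the convention is documented rather than
  printed.
* NRF ineligibility (< 10 kcal/100 g) produces a flagged `NA`, never
  `NaN`; a constant vector has no Spearman correlation and is flagged;
  zero-variance paired differences are flagged rather than erroring.
* Missing fiber is scored as 0 in Nutri-Score with a warning; missing
  core nutrients are an error there, because scoring is defined
  post-imputation.
* Problem sizes in the test suite: cohorts at the published category
  sizes (1042 + 550) for recovery and ordering checks, 1000 products for
  the mode-contrast check, 50 random vectors for the NRF oracle; the
  whole suite and the acceptance script each run in well under a minute.

## Limitations

* Category membership comes from the data supplier's category strings;
  re-categorized snapshots of the source database will shift counts.
* The added-sugar and fruit-term lists are finite; unusual sweeteners
  (agave, monk fruit) and exotic fruit waters need lexicon extensions,
  which `read_lexicon()` supports without code changes.
* Nutri-Score here is the 2017 algorithm, matching the cited scheme; the
  2023 revision is out of scope, as are NRF variants beyond NRF5.3
  (though the reference table makes them easy to add).
* Standards are defined for milk alternatives only; there are no
  published standards for PB waters.
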