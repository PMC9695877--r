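# Shared fixture builders. Everything is generated in code; the only stored
# fixture is the small CSV of printed label ingredient statements under
# inst/extdata.

make_product <- function(product_id = "p1",
                         long_name = "Test beverage",
                         brand = "Test brand",
                         usda_category = "pb_milk_alternative",
                         energy_kcal_100g = 50,
                         protein_g = 1, total_fat_g = 2, satfat_g = 0.2,
                         total_sugars_g = 2, fiber_g = 0.5,
                         calcium_mg = 100, sodium_mg = 50,
                         vit_a_iu = 150, vit_d_iu = 40, vit_b12_mcg = 0.5,
                         vit_c_mg = 0, vit_e_mg = 0, zinc_mg = 0,
                         riboflavin_mg = 0.1,
                         ingredients_text = "filtered water, almonds") {
  tibble::tibble(
    product_id = product_id, long_name = long_name, brand = brand,
    usda_category = usda_category, energy_kcal_100g = energy_kcal_100g,
    protein_g = protein_g, total_fat_g = total_fat_g, satfat_g = satfat_g,
    total_sugars_g = total_sugars_g, fiber_g = fiber_g,
    calcium_mg = calcium_mg, sodium_mg = sodium_mg, vit_a_iu = vit_a_iu,
    vit_d_iu = vit_d_iu, vit_b12_mcg = vit_b12_mcg, vit_c_mg = vit_c_mg,
    vit_e_mg = vit_e_mg, zinc_mg = zinc_mg, riboflavin_mg = riboflavin_mg,
    ingredients_text = ingredients_text
  )
}

# The three printed label ingredient statements (real products).
label_fixture <- function() {
  path <- system.file("extdata", "example_label_ingredients.csv",
                      package = "nutridense")
  df <- readr::read_csv(path, show_col_types = FALSE)
  df$product_id <- as.character(df$product_id)
  df$long_name[is.na(df$long_name)] <- ""
  df
}

# Category mean vectors from the published summary table, for score anchors.
category_mean_product <- function(category, type = "milk") {
  par <- pb_reference_parameters(type)
  row <- par[par$category == category, ]
  make_product(
    product_id = paste0("mean_", category),
    energy_kcal_100g = row$energy_mean, protein_g = row$protein_mean,
    total_fat_g = row$fat_mean, satfat_g = row$satfat_mean,
    total_sugars_g = row$sugars_mean, calcium_mg = row$calcium_mean,
    sodium_mg = row$sodium_mean,
    usda_category = if (type == "milk") "pb_milk_alternative" else "pb_water"
  )
}
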