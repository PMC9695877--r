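test_that("tokenizer splits on top-level commas and flattens parentheticals in order", {
  toks <- tokenize_ingredients(
    "Flax milk (filtered water, cold pressed flax oil), pea protein isolate, cane sugar"
  )
  expect_equal(toks, c("flax milk", "filtered water", "cold pressed flax oil",
                       "pea protein isolate", "cane sugar"))
  expect_equal(toks[1], "flax milk")

  expect_equal(tokenize_ingredients(""), character())
  expect_equal(tokenize_ingredients(NA_character_), character())

  # nested parentheses and brackets
  expect_equal(
    tokenize_ingredients("blend [water, oil (sunflower, canola)], salt"),
    c("blend", "water", "oil", "sunflower", "canola", "salt")
  )
  expect_warning(tokenize_ingredients("water (oil, salt"), "unbalanced")
})

test_that("tokenization is idempotent on its own top-level output", {
  set.seed(11)
  lex <- default_lexicon()
  pool <- c(lex$added_sugar, lex$sodium, unlist(lex$fortificants),
            "filtered water", "natural flavors", "gellan gum")
  for (i in 1:25) {
    toks <- sample(pool, sample(2:8, 1))
    text <- paste(toks, collapse = ", ")
    once <- tokenize_ingredients(text)
    twice <- tokenize_ingredients(paste(once, collapse = ", "))
    expect_equal(twice, once)
  }
})

test_that("printed label statements yield the expected flags", {
  flags <- detect_flags(label_fixture())
  flags <- flags[match(c("496925", "1097251", "411752"), flags$product_id), ]
  expect_equal(flags$has_added_sugar, c(TRUE, TRUE, FALSE))
  expect_equal(flags$has_added_sodium, c(TRUE, TRUE, TRUE))
  # almond milk: calcium, A, D, E, B12; no C
  expect_true(all(unlist(flags[1, c("fort_calcium", "fort_vitamin_a",
                                    "fort_vitamin_d", "fort_vitamin_e",
                                    "fort_vitamin_b12")])))
  expect_false(flags$fort_vitamin_c[1])
  # flax milk: A, D, B12; no calcium
  expect_true(all(unlist(flags[2, c("fort_vitamin_a", "fort_vitamin_d",
                                    "fort_vitamin_b12")])))
  expect_false(flags$fort_calcium[2])
  # cashew milk: calcium, A, D, E, C; no sugar, no B12
  expect_true(all(unlist(flags[3, c("fort_calcium", "fort_vitamin_a",
                                    "fort_vitamin_d", "fort_vitamin_e",
                                    "fort_vitamin_c")])))
  expect_false(flags$fort_vitamin_b12[3])
  # matched terms are recorded exactly when a flag is true
  expect_match(flags$added_sugar_terms[1], "cane sugar")
  expect_equal(flags$added_sugar_terms[3], "")
})

test_that("empty ingredient statements produce all-false flags", {
  flags <- detect_flags(make_product(ingredients_text = ""))
  flag_cols <- grep("^(has_|fort_)", names(flags), value = TRUE)
  flag_cols <- setdiff(flag_cols, grep("_terms$", names(flags), value = TRUE))
  expect_false(any(unlist(flags[, flag_cols])))
})

test_that("term matching respects word boundaries and plurals", {
  p <- function(txt) make_product(ingredients_text = txt)
  # "sunflower lecithin" must not trip the salt search
  expect_false(detect_flags(p("sunflower lecithin"))$has_added_sodium)
  # bare sodium inside a nutrient salt counts by default
  expect_true(detect_flags(p("sodium ascorbate"))$has_added_sodium)
  # plural base forms still match
  expect_true(detect_flags(p("organic dates"))$has_added_sugar)
  # but embedded substrings do not
  expect_false(detect_flags(p("sugarcane fiber"))$has_added_sugar)
})

test_that("flags are deterministic and monotone under added tokens", {
  set.seed(23)
  lex <- default_lexicon()
  pool <- c(lex$added_sugar, lex$sodium, unlist(lex$fortificants),
            "filtered water", "xanthan gum")
  flag_cols <- function(f) {
    cols <- grep("^(has_|fort_)", names(f), value = TRUE)
    setdiff(cols, grep("_terms$", cols, value = TRUE))
  }
  for (i in 1:20) {
    base <- paste(sample(pool, 4), collapse = ", ")
    extra <- paste(base, sample(pool, 1), sep = ", ")
    f1 <- detect_flags(make_product(ingredients_text = base))
    f1b <- detect_flags(make_product(ingredients_text = base))
    f2 <- detect_flags(make_product(ingredients_text = extra))
    expect_identical(f1, f1b)
    cols <- flag_cols(f1)
    expect_true(all(unlist(f2[, cols]) >= unlist(f1[, cols])))
  }
})

test_that("plant source follows the first-listed-plant rule", {
  classify1 <- function(long_name, ingredients,
                        category = "pb_milk_alternative") {
    classify_plant_source(make_product(long_name = long_name,
                                       usda_category = category,
                                       ingredients_text = ingredients))$plant_source
  }
  expect_equal(classify1("Flax milk", "flax milk (filtered water, cold pressed flax oil), pea protein isolate"),
               "flax_hemp")
  # no hint in the name: first plant ingredient decides
  expect_equal(classify1("golden milk", "filtered water, coconut cream, turmeric"),
               "coconut")
  # adversarial: peanut must not resolve to pea
  expect_equal(classify1("peanut beverage", "filtered water, peanuts"),
               "tree_nut")
  # blends: earlier in predominance order wins
  expect_equal(classify1("nut blend beverage", "filtered water, almonds, coconut cream"),
               "almond")
  # emulsifiers never classify
  expect_equal(classify1("mystery drink", "filtered water, soy lecithin, oats"),
               "oat")
  # ambiguous name (two families) defers to ingredients
  expect_equal(classify1("Almond & coconut blend", "filtered water, coconut cream, almonds"),
               "coconut")
  expect_equal(classify1("", ""), "unknown")
})

test_that("water subtypes classify to coconut/aloe/tree/fruit/plain_flavored", {
  classify1 <- function(long_name, ingredients) {
    classify_plant_source(make_product(long_name = long_name,
                                       usda_category = "pb_water",
                                       ingredients_text = ingredients))$plant_source
  }
  expect_equal(classify1("Coconut water", "coconut water"), "coconut")
  expect_equal(classify1("Aloe drink", "water, aloe vera juice, cane sugar"), "aloe")
  expect_equal(classify1("Maple water", "maple sap"), "tree")
  expect_equal(classify1("Fruit water", "water, watermelon juice"), "fruit")
  expect_equal(classify1("Essence water", "water, natural flavors"), "plain_flavored")
})

test_that("lexicon round-trips through a YAML config file", {
  path <- withr::local_tempfile(fileext = ".yaml")
  lex <- default_lexicon()
  lex$added_sugar <- c("sugar", "agave nectar")
  yaml::write_yaml(list(added_sugar = lex$added_sugar), path)
  loaded <- read_lexicon(path)
  expect_equal(loaded$added_sugar, c("sugar", "agave nectar"))
  expect_equal(loaded$sodium, default_lexicon()$sodium)
  f <- detect_flags(make_product(ingredients_text = "water, agave nectar"), loaded)
  expect_true(f$has_added_sugar)
})
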