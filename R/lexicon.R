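#' Default ingredient-search lexicon
#'
#' Term lists used to mine ingredient statements for added sugars, added
#' sodium and fortificants, and to identify the main plant source of a
#' beverage. Terms are matched case-insensitively on word boundaries within
#' each ingredient token, with an optional plural "s" (so "almond" matches
#' "organic almonds" but "pea" never matches "peanut" and "oat" never matches
#' "goats"). All lists can be edited and passed back to the search functions,
#' or loaded from a YAML/JSON file with [read_lexicon()].
#'
#' @details The structure is a named list:
#' \describe{
#'   \item{added_sugar}{caloric sweetener terms (cane sugar, syrups, honey, dates).}
#'   \item{sodium}{salt and sodium terms.}
#'   \item{sodium_exclude}{tokens in which a bare "sodium" hit is ignored
#'     (default empty: sodium salts of added nutrients do count as added
#'     sodium).}
#'   \item{fortificants}{one character vector of chemical fortificant names per
#'     nutrient: calcium, vitamin_a, vitamin_d, vitamin_e, vitamin_c,
#'     vitamin_b12, zinc.}
#'   \item{plant_milk}{named character vector mapping a plant search term to
#'     the milk-alternative family it belongs to (flax and hemp collapse to
#'     flax_hemp; pistachio-type nuts to tree_nut; sunflower/sesame and fruit
#'     bases to seeds_fruit).}
#'   \item{plant_water}{named character vector mapping water-specific terms
#'     (sap trees, aloe, fruits, coconut) to the PB-water subtype.}
#'   \item{classification_exclude}{ingredient tokens never used for
#'     plant-source classification (emulsifiers such as "soy lecithin").}
#' }
#'
#' @return A list of term vectors as described above.
#' @export
#' @examples
#' lex <- default_lexicon()
#' names(lex)
#' lex$added_sugar[1:3]
default_lexicon <- function() {
  fruit_terms <- c(
    "watermelon", "strawberry", "raspberry", "blueberry", "blackberry",
    "cherry", "mango", "pineapple", "banana", "apple", "grape", "orange",
    "lemon", "lime", "peach", "pear", "guava", "dragon fruit", "pomegranate",
    "cranberry", "acai", "passion fruit", "kiwi"
  )
  milk_families <- c(
    almond = "almond", cashew = "cashew", coconut = "coconut",
    flax = "flax_hemp", hemp = "flax_hemp",
    macadamia = "macadamia", walnut = "walnut",
    peanut = "tree_nut", pistachio = "tree_nut", pecan = "tree_nut",
    hazelnut = "tree_nut",
    rice = "rice", quinoa = "quinoa", oat = "oat", pea = "pea", soy = "soy",
    sunflower = "seeds_fruit", sesame = "seeds_fruit", banana = "seeds_fruit"
  )
  water_subtypes <- c(
    coconut = "coconut", aloe = "aloe",
    maple = "tree", birch = "tree", cactus = "tree",
    stats::setNames(rep("fruit", length(fruit_terms)), fruit_terms)
  )
  list(
    added_sugar = c(
      "sugar", "cane sugar", "pure cane sugar", "dried cane syrup",
      "evaporated cane syrup", "evaporated cane juice",
      "evaporated cane juice syrup", "brown rice syrup", "honey",
      "organic maple syrup", "maple syrup", "date syrup", "organic dates"
    ),
    sodium = c("salt", "sea salt", "himalayan pink salt", "sodium"),
    sodium_exclude = character(),
    fortificants = list(
      calcium = c("calcium carbonate", "tricalcium phosphate", "calcium lactate"),
      vitamin_a = c("vitamin a palmitate", "vitamin a acetate"),
      vitamin_d = c("ergocalciferol", "cholecalciferol", "vitamin d2", "vitamin d3"),
      vitamin_e = c("alpha-tocopherol", "tocopherol", "vitamin e"),
      vitamin_c = c("ascorbic acid", "ascorbate", "vitamin c"),
      vitamin_b12 = c("vitamin b12", "cyanocobalamin", "methylcobalamin"),
      zinc = c("zinc oxide", "zinc sulfate", "zinc gluconate")
    ),
    plant_milk = milk_families,
    plant_water = water_subtypes,
    classification_exclude = c("soy lecithin", "sunflower lecithin", "sunflower oil")
  )
}

#' Load a lexicon from a YAML or JSON file
#'
#' Reads a user-edited lexicon. Missing components fall back to
#' [default_lexicon()]; terms are lowercased.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose top-level keys
#'   are a subset of the names of [default_lexicon()].
#' @return A lexicon list.
#' @export
read_lexicon <- function(path) {
  stopifnot(file.exists(path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  lex <- default_lexicon()
  for (nm in intersect(names(raw), names(lex))) {
    val <- raw[[nm]]
    if (nm %in% c("plant_milk", "plant_water")) {
      val <- stats::setNames(tolower(unlist(val)), tolower(names(unlist(val))))
    } else if (nm == "fortificants") {
      val <- lapply(val, function(v) tolower(unlist(v)))
    } else {
      val <- tolower(unlist(val))
      if (is.null(val)) val <- character()
    }
    lex[[nm]] <- val
  }
  lex
}

#' Tokenize an ingredient statement
#'
#' Splits a labeled ingredient statement into lowercased ingredient phrases in
#' order of predominance (US labels list ingredients in decreasing order of
#' amount). Top-level phrases are split on commas outside parentheses or
#' brackets; parenthetical sub-ingredients are retained and flattened into the
#' stream immediately after the phrase that contains them, so "flax milk
#' (filtered water, flax oil), cane sugar" yields "flax milk", "filtered
#' water", "flax oil", "cane sugar" with "flax milk" first.
#'
#' Unbalanced parentheses trigger a warning and a best-effort split.
#'
#' @param text A character vector of ingredient statements (NA treated as "").
#' @return For a single statement, a character vector of tokens; for a vector,
#'   a list of such vectors.
#' @export
#' @examples
#' tokenize_ingredients(
#'   "Flax milk (filtered water, cold pressed flax oil), pea protein isolate, cane sugar"
#' )
tokenize_ingredients <- function(text) {
  out <- lapply(text, tokenize_one)
  if (length(text) == 1L) out[[1L]] else out
}

# Recursive-descent split: commas at depth 0 delimit phrases; a parenthesised
# group is tokenized itself and its tokens appended after the host phrase.
tokenize_one <- function(text) {
  if (is.na(text) || !nzchar(trimws(text))) return(character())
  text <- tolower(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  open <- c("(" = ")", "[" = "]")
  tokens <- character()
  buf <- character()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% names(open)) {
      # find matching close, tolerating nesting
      depth <- 1L
      j <- i
      while (depth > 0L && j < n) {
        j <- j + 1L
        if (chars[j] %in% names(open)) depth <- depth + 1L
        if (chars[j] %in% open) depth <- depth - 1L
      }
      if (depth > 0L) {
        warning("unbalanced parentheses in ingredient statement; best-effort split",
                call. = FALSE)
      }
      inner <- paste(chars[seq.int(i + 1L, max(i, j - 1L))], collapse = "")
      parent <- clean_token(paste(buf, collapse = ""))
      if (nzchar(parent)) tokens <- c(tokens, parent)
      buf <- character()
      tokens <- c(tokens, tokenize_one(inner))
      i <- j + 1L
    } else if (ch == ",") {
      tok <- clean_token(paste(buf, collapse = ""))
      if (nzchar(tok)) tokens <- c(tokens, tok)
      buf <- character()
      i <- i + 1L
    } else {
      buf <- c(buf, ch)
      i <- i + 1L
    }
  }
  tok <- clean_token(paste(buf, collapse = ""))
  if (nzchar(tok)) tokens <- c(tokens, tok)
  tokens
}

clean_token <- function(x) {
  x <- gsub("\\s+", " ", x)
  x <- sub("^\\s*(contains\\s+[0-9.]+%\\s+or\\s+less\\s+of:?|incl\\.|including)\\s*",
           "", x)
  x <- gsub("^[[:space:][:punct:]]+|[[:space:][:punct:]]+$", "", x)
  trimws(x)
}

# Word-boundary, plural-tolerant regex for one lowercase term.
term_regex <- function(term) {
  paste0("\\b", gsub("([^[:alnum:][:space:]])", "\\\\\\1", term), "s?\\b")
}

# Which tokens contain `term`? Returns logical vector over tokens.
term_hits <- function(tokens, term) {
  stringr::str_detect(tokens, stringr::regex(term_regex(term), ignore_case = TRUE))
}

match_terms <- function(tokens, terms) {
  if (length(tokens) == 0L) return(character())
  hit <- vapply(terms, function(tm) any(term_hits(tokens, tm)), logical(1))
  unname(terms[hit])
}

#' Search ingredient statements for added sugars, sodium and fortificants
#'
#' Runs the lexicon term searches over each product's ingredient statement.
#' A flag is true iff at least one ingredient token contains a term from the
#' corresponding list, matched case-insensitively on word boundaries. The bare
#' term "sodium" counts as added sodium even when it occurs inside the sodium
#' salt of an added nutrient, unless the token is listed in
#' `lexicon$sodium_exclude`.
#'
#' @param products A tibble with at least `product_id` and `ingredients_text`.
#' @param lexicon A lexicon list, see [default_lexicon()].
#' @return A tibble with one row per product: `product_id`, logical
#'   `has_added_sugar` and `has_added_sodium`, logical `fort_<nutrient>`
#'   columns for the seven fortificant nutrients, and semicolon-joined
#'   `*_terms` columns recording which terms matched (empty string iff the
#'   flag is false).
#' @export
detect_flags <- function(products, lexicon = default_lexicon()) {
  stopifnot(all(c("product_id", "ingredients_text") %in% names(products)))
  token_sets <- lapply(products$ingredients_text, tokenize_one)

  one <- function(tokens) {
    sugar <- match_terms(tokens, lexicon$added_sugar)
    keep <- !(tokens %in% lexicon$sodium_exclude)
    sodium <- match_terms(tokens[keep], lexicon$sodium)
    fort <- lapply(lexicon$fortificants, function(terms) match_terms(tokens, terms))
    c(
      list(has_added_sugar = length(sugar) > 0L,
           added_sugar_terms = paste(sugar, collapse = ";"),
           has_added_sodium = length(sodium) > 0L,
           added_sodium_terms = paste(sodium, collapse = ";")),
      stats::setNames(lapply(fort, function(m) length(m) > 0L),
                      paste0("fort_", names(fort))),
      stats::setNames(lapply(fort, function(m) paste(m, collapse = ";")),
                      paste0("fort_", names(fort), "_terms"))
    )
  }
  res <- purrr::map(token_sets, one)
  dplyr::bind_cols(
    tibble::tibble(product_id = products$product_id),
    dplyr::bind_rows(res)
  )
}

#' Classify the main plant source of each beverage
#'
#' Implements the first-listed-plant rule: the product long name is searched
#' for plant terms first (longest term wins within a token); if the name
#' points to exactly one plant family, that family is assigned. Otherwise the
#' ingredient tokens are scanned in order of predominance and the first token
#' containing a plant term decides. Emulsifier tokens such as "soy lecithin"
#' are never used for classification. Flax and hemp collapse to `flax_hemp`,
#' pistachio-type nuts to `tree_nut`, seed and fruit bases to `seeds_fruit`.
#' PB waters use the water term list (`coconut`, `aloe`, `tree`, `fruit`);
#' a water with ingredients but no plant hit is `plain_flavored`. A product
#' with no usable signal is `unknown`.
#'
#' @param products Tibble with `product_id`, `long_name`, `usda_category`
#'   (`"pb_milk_alternative"` or `"pb_water"`) and `ingredients_text`.
#' @param lexicon A lexicon list.
#' @return The input `product_id`s with a `plant_source` character column.
#' @export
classify_plant_source <- function(products, lexicon = default_lexicon()) {
  stopifnot(all(c("product_id", "long_name", "usda_category", "ingredients_text")
                %in% names(products)))
  src <- purrr::pmap_chr(
    list(products$long_name, products$ingredients_text, products$usda_category),
    function(nm, ing, cat) {
      terms <- if (identical(cat, "pb_water")) lexicon$plant_water else lexicon$plant_milk
      classify_one(nm, tokenize_one(ing), cat, terms, lexicon$classification_exclude)
    }
  )
  tibble::tibble(product_id = products$product_id, plant_source = src)
}

classify_one <- function(long_name, tokens, category, term_map, exclude) {
  terms <- names(term_map)[order(-nchar(names(term_map)))]  # longest first
  fams_in <- function(txt) {
    hit <- vapply(terms, function(tm) any(term_hits(txt, tm)), logical(1))
    unique(unname(term_map[terms[hit]]))
  }
  # (1) product long name, only if it names exactly one family
  if (!is.na(long_name) && nzchar(long_name)) {
    fams <- fams_in(tolower(long_name))
    if (length(fams) == 1L) return(fams)
  }
  # (2) first plant term in order of predominance
  usable <- tokens[!(tokens %in% exclude)]
  for (tok in usable) {
    for (tm in terms) {
      if (any(term_hits(tok, tm))) return(unname(term_map[[tm]]))
    }
  }
  # (3) waters with real ingredients but no plant base are flavored waters
  if (identical(category, "pb_water") && length(tokens) > 0L) return("plain_flavored")
  "unknown"
}
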