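#' Apply the analytical-sample exclusion rules
#'
#' Drops beverages whose energy density is missing or reported above
#' 250 kcal/100 g (a value more consistent with solid foods). The boundary is
#' strict: exactly 250 kcal/100 g is kept. Every input record lands in
#' exactly one of the two outputs.
#'
#' @param products Product tibble.
#' @return A list with `kept` (product tibble) and `excluded` (product tibble
#'   plus a machine-readable `reason` column: `missing_energy` or
#'   `energy_gt_250`).
#' @export
apply_exclusions <- function(products) {
  e <- products$energy_kcal_100g
  reason <- dplyr::case_when(
    is.na(e) ~ "missing_energy",
    e > 250 ~ "energy_gt_250",
    TRUE ~ NA_character_
  )
  excluded <- products[!is.na(reason), , drop = FALSE]
  excluded$reason <- reason[!is.na(reason)]
  list(kept = products[is.na(reason), , drop = FALSE], excluded = excluded)
}

imputable_vitamins <- function() {
  c(vitamin_a = "vit_a_iu", vitamin_d = "vit_d_iu", vitamin_b12 = "vit_b12_mcg")
}

#' Build the vitamin imputation policy from category medians
#'
#' For vitamins A, D and B12, computes the median declared amount per product
#' type (by default the plant-source category) among donor products. Donors
#' are products whose value is present (not `NA`) and — under the default
#' `donors = "fortified"` — whose ingredient list declares the corresponding
#' fortificant; unfortified products legitimately sit near 0 and would drag
#' the median down. `donors = "declared"` uses every non-missing value
#' instead. When a category has no donors for a vitamin, the fallback is the
#' global median over all donors in the same USDA category; if there are no
#' donors anywhere the vitamin is marked `no_donor` and label-declared
#' missing values impute to 0 with a warning at imputation time.
#'
#' @param products Product tibble with a `plant_source` column (or the column
#'   named in `by`).
#' @param flags Output of [detect_flags()] for the same products.
#' @param by Grouping column defining "product type" (default
#'   `"plant_source"`; `"usda_category"` gives the coarser two-way grouping).
#' @param donors `"fortified"` (default) or `"declared"`.
#' @return An `imputation_policy`: a tibble with columns `vitamin`, `group`,
#'   `median`, `n_donors` (group `"__global__"` rows hold the fallback), with
#'   the grouping column name stored in `attr(, "by")`.
#' @export
compute_medians <- function(products, flags, by = "plant_source",
                            donors = c("fortified", "declared")) {
  donors <- match.arg(donors)
  stopifnot(by %in% names(products))
  vit <- imputable_vitamins()
  joined <- dplyr::left_join(products, flags, by = "product_id")
  rows <- list()
  for (v in names(vit)) {
    col <- vit[[v]]
    ok <- !is.na(joined[[col]])
    if (donors == "fortified") ok <- ok & joined[[paste0("fort_", v)]]
    vals <- joined[[col]][ok]
    grp <- joined[[by]][ok]
    if (length(vals) > 0L) {
      med <- tapply(vals, grp, stats::median)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        vitamin = v, group = names(med), median = as.numeric(med),
        n_donors = as.integer(table(grp)[names(med)])
      )
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      vitamin = v, group = "__global__",
      median = if (length(vals) > 0L) stats::median(vals) else NA_real_,
      n_donors = length(vals)
    )
  }
  policy <- dplyr::bind_rows(rows)
  attr(policy, "by") <- by
  class(policy) <- c("imputation_policy", class(policy))
  policy
}

#' Impute undeclared vitamin values
#'
#' For vitamins A, D and B12: a missing value whose fortificant appears on
#' the ingredient list is set to the category median from `policy`; a missing
#' value with no label declaration is set to 0; declared (non-missing) values
#' are never altered. Each vitamin gains a provenance column
#' (`vit_*_provenance`) with values `declared`, `imputed_median` or
#' `imputed_zero`. Imputation is idempotent and touches no other field.
#'
#' @param products Product tibble (with the policy's grouping column).
#' @param flags Output of [detect_flags()].
#' @param policy Output of [compute_medians()].
#' @return The product tibble with vitamins filled and provenance columns.
#' @export
impute_vitamins <- function(products, flags, policy) {
  by <- attr(policy, "by")
  stopifnot(!is.null(by), by %in% names(products))
  out <- dplyr::left_join(products,
                          flags[, c("product_id",
                                    paste0("fort_", names(imputable_vitamins())))],
                          by = "product_id")
  for (v in names(imputable_vitamins())) {
    col <- imputable_vitamins()[[v]]
    prov_col <- paste0(col, "_provenance")
    pol <- policy[policy$vitamin == v, , drop = FALSE]
    global_med <- pol$median[pol$group == "__global__"]
    lut <- stats::setNames(pol$median[pol$group != "__global__"],
                           pol$group[pol$group != "__global__"])
    miss <- is.na(out[[col]])
    declared_on_label <- out[[paste0("fort_", v)]]
    med <- unname(lut[out[[by]]])
    med[is.na(med)] <- global_med
    if (any(miss & declared_on_label & is.na(med))) {
      warning(sprintf("no donors anywhere for %s; declared-but-missing values set to 0", v),
              call. = FALSE)
      med[is.na(med)] <- 0
    }
    prov <- if (prov_col %in% names(out)) out[[prov_col]] else
      rep(NA_character_, nrow(out))
    prov[!miss & is.na(prov)] <- "declared"
    fill <- ifelse(declared_on_label, med, 0)
    prov[miss] <- ifelse(declared_on_label[miss], "imputed_median", "imputed_zero")
    out[[col]][miss] <- fill[miss]
    out[[prov_col]] <- prov
  }
  out[, setdiff(names(out), paste0("fort_", names(imputable_vitamins())))]
}
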