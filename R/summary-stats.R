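#' Group means and standard errors
#'
#' Mean and standard error (SE = SD/sqrt(n)) per group per variable, with an
#' "All" row, mirroring the layout of published category summary tables.
#' Single-member groups report SE 0 for display with `se_undefined = TRUE`
#' in the machine output.
#'
#' @param products Product tibble.
#' @param grouping Name of the grouping column (e.g. `"plant_source"`).
#' @param variables Character vector of numeric columns to summarize.
#' @param order_by Optional variable name; groups are sorted by descending
#'   group mean of that variable (the "All" row stays first).
#' @return Tibble: `group`, `n`, `variable`, `mean`, `se`, `se_undefined`.
#' @export
summarize_groups <- function(products, grouping, variables, order_by = NULL) {
  stopifnot(grouping %in% names(products))
  missing_vars <- setdiff(variables, names(products))
  if (length(missing_vars) > 0L) {
    stop("unknown variable(s): ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  one <- function(label, df) {
    purrr::map_dfr(variables, function(v) {
      x <- df[[v]][!is.na(df[[v]])]
      n <- length(x)
      tibble::tibble(
        group = label, n = n, variable = v,
        mean = if (n > 0) mean(x) else NA_real_,
        se = if (n > 1) stats::sd(x) / sqrt(n) else if (n == 1) 0 else NA_real_,
        se_undefined = n <= 1
      )
    })
  }
  out <- one("All", products)
  groups <- unique(products[[grouping]])
  for (g in groups) out <- dplyr::bind_rows(out, one(g, products[products[[grouping]] == g, ]))
  if (!is.null(order_by)) {
    key <- out[out$variable == order_by & out$group != "All", c("group", "mean")]
    lev <- c("All", key$group[order(-key$mean)])
    out <- out[order(match(out$group, lev)), ]
  }
  out
}

#' One-way ANOVA with Bonferroni post hoc comparisons
#'
#' Classical one-way ANOVA of a numeric variable over a grouping factor,
#' followed by pairwise t tests with Bonferroni-adjusted p values (Tukey HSD
#' available as an alternative). The significance threshold used throughout
#' the reporting is p < 0.01.
#'
#' @param data A data frame.
#' @param value Name of the numeric column.
#' @param group Name of the grouping column (at least 2 groups with at least
#'   2 members each).
#' @param posthoc `"bonferroni"` (default) or `"tukey"`.
#' @return List: `f`, `df1`, `df2`, `p`, and `posthoc` (tibble of pairwise
#'   comparisons with adjusted p values).
#' @export
anova_oneway <- function(data, value, group, posthoc = c("bonferroni", "tukey")) {
  posthoc <- match.arg(posthoc)
  x <- data[[value]]
  g <- factor(data[[group]])
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2L || any(table(g) < 2L)) {
    stop("one-way ANOVA needs >= 2 groups with >= 2 members each", call. = FALSE)
  }
  fit <- stats::aov(x ~ g)
  tab <- summary(fit)[[1L]]
  ph <- if (posthoc == "bonferroni") {
    pt <- stats::pairwise.t.test(x, g, p.adjust.method = "bonferroni",
                                 pool.sd = TRUE)
    as.data.frame(as.table(pt$p.value)) |>
      stats::setNames(c("group1", "group2", "p_adj")) |>
      dplyr::filter(!is.na(.data$p_adj)) |>
      tibble::as_tibble()
  } else {
    th <- stats::TukeyHSD(fit)$g
    tibble::tibble(
      comparison = rownames(th),
      diff = th[, "diff"], p_adj = th[, "p adj"]
    )
  }
  list(f = tab[["F value"]][1L], df1 = tab[["Df"]][1L], df2 = tab[["Df"]][2L],
       p = tab[["Pr(>F)"]][1L], posthoc = ph)
}

#' Spearman rank correlation
#'
#' Spearman correlation with average ranks for ties. A constant vector has
#' no defined rank correlation: the result is `NA` with `defined = FALSE`.
#'
#' @param x,y Aligned numeric vectors, n >= 3 (pairs with missing values are
#'   dropped).
#' @return List: `rho`, `n`, `defined`.
#' @export
spearman_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  stopifnot(length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, n = length(x), defined = FALSE))
  }
  list(rho = stats::cor(x, y, method = "spearman"), n = length(x),
       defined = TRUE)
}

#' Paired t test
#'
#' Classical paired t statistic and two-sided p value for aligned score
#' vectors; the convention used when comparing Nutri-Score modes is
#' differences = solid-mode minus beverage-mode, so a negative t means solid
#' scoring is more favorable (lower points). Zero-variance differences are
#' flagged rather than producing an error.
#'
#' @param scores_a,scores_b Aligned numeric vectors, n >= 2.
#' @return List: `t`, `df`, `p`, `mean_diff`, `defined`.
#' @export
paired_t <- function(scores_a, scores_b) {
  ok <- !is.na(scores_a) & !is.na(scores_b)
  a <- scores_a[ok]; b <- scores_b[ok]
  stopifnot(length(a) >= 2L)
  d <- a - b
  if (stats::sd(d) == 0) {
    return(list(t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                df = length(d) - 1L, p = if (mean(d) == 0) 1 else 0,
                mean_diff = mean(d), defined = FALSE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = mean(d), defined = TRUE)
}
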