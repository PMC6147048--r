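#' Trait-by-environment proportion table
#'
#' For one environmental factor (habitat or oxygen requirement), the fraction
#' of organisms carrying a feature per factor category, with exact binomial
#' confidence intervals. Organisms whose factor value is `"unknown"` are
#' excluded from denominators. The analysis is restricted to bacteria by
#' default: archaea are dominated by aquatic/anaerobic Mo users, which would
#' bias a pooled prokaryote table.
#'
#' @param trait_calls Output of [call_mo_utilization()].
#' @param metadata Organism metadata.
#' @param factor_name `"habitat"` or `"oxygen_req"`.
#' @param feature Name of a logical column of `trait_calls` to summarise:
#'   `"mo_utilizing"` (default), a transporter (`"ModABC"`, ...), an enzyme
#'   family (`"DMSOR"`, ...), or `"rich"`.
#' @param kingdom Kingdom filter (default `"bacteria"`; `NULL` for all).
#' @param decimals Decimal places for the percentage (default 2, the style
#'   of environment tables such as 94.05%).
#' @param conf_level Confidence level of the exact binomial interval.
#' @return A `mo_factor_table` tibble: `category`, `n_total`,
#'   `n_with_feature`, `percent`, `ci_lower`, `ci_upper` (CI bounds on the
#'   percent scale), with attributes `factor` and `feature`.
#' @export
trait_by_factor <- function(trait_calls, metadata,
                            factor_name = c("habitat", "oxygen_req"),
                            feature = "mo_utilizing",
                            kingdom = "bacteria",
                            decimals = 2, conf_level = 0.95) {
  factor_name <- match.arg(factor_name)
  if (!feature %in% names(trait_calls)) {
    abort(sprintf("feature column '%s' not found in trait calls", feature))
  }
  df <- as_tibble(trait_calls) |>
    left_join(select(metadata, "organism_id", factor_val = all_of(factor_name)),
              by = "organism_id")
  if (!is.null(kingdom)) df <- filter(df, .data$kingdom == !!kingdom)
  df <- filter(df, .data$factor_val != "unknown")
  if (nrow(df) == 0) {
    warn(sprintf("no organism with known %s; empty table", factor_name))
    out <- tibble(category = character(), n_total = integer(),
                  n_with_feature = integer(), percent = numeric(),
                  ci_lower = numeric(), ci_upper = numeric())
  } else {
    levels_known <- setdiff(
      if (factor_name == "habitat") habitat_levels() else oxygen_levels(),
      "unknown")
    out <- df |>
      group_by(category = factor(.data$factor_val, levels = levels_known)) |>
      summarise(n_total = dplyr::n(),
                n_with_feature = sum(.data[[feature]], na.rm = TRUE),
                .groups = "drop") |>
      mutate(category = as.character(.data$category),
             percent = percent_of(.data$n_with_feature, .data$n_total,
                                  decimals))
    ci <- purrr::map2(out$n_with_feature, out$n_total, function(x, n) {
      100 * stats::binom.test(x, n, conf.level = conf_level)$conf.int
    })
    out$ci_lower <- vapply(ci, `[`, numeric(1), 1)
    out$ci_upper <- vapply(ci, `[`, numeric(1), 2)
  }
  attr(out, "factor") <- factor_name
  attr(out, "feature") <- feature
  attr(out, "conf_level") <- conf_level
  class(out) <- c("mo_factor_table", class(out))
  out
}

#' Rank factor categories by feature prevalence
#'
#' Stable descending sort by percent (ties keep input category order), with a
#' one-line statement of the extremes in the `statement` attribute.
#'
#' @param factor_table A [trait_by_factor()] table.
#' @return The table sorted by descending percent with a `rank` column.
#' @export
rank_categories <- function(factor_table) {
  if (nrow(factor_table) == 0) abort("cannot rank an empty factor table")
  ord <- order(-factor_table$percent)
  out <- factor_table[ord, ]
  out$rank <- seq_len(nrow(out))
  attr(out, "statement") <- sprintf(
    "highest: %s (%.2f%%); lowest: %s (%.2f%%)",
    out$category[1], out$percent[1],
    out$category[nrow(out)], out$percent[nrow(out)])
  out
}

#' Compare two factor categories (extension)
#'
#' Two-sided two-proportion chi-square test between two categories of a
#' factor table. This is an add-on convenience: the core analysis reports
#' proportions only.
#'
#' @param factor_table A [trait_by_factor()] table.
#' @param cat_a,cat_b Category names to compare.
#' @param correct Apply continuity correction (default `FALSE`).
#' @return A one-row tibble with estimates, the chi-square statistic and
#'   p-value.
#' @export
compare_categories <- function(factor_table, cat_a, cat_b, correct = FALSE) {
  rows <- factor_table[match(c(cat_a, cat_b), factor_table$category), ]
  if (any(is.na(rows$n_total))) {
    abort("both categories must be present in the factor table")
  }
  ht <- stats::prop.test(rows$n_with_feature, rows$n_total, correct = correct)
  tibble(category_a = cat_a, category_b = cat_b,
         prop_a = unname(ht$estimate[1]), prop_b = unname(ht$estimate[2]),
         statistic = unname(ht$statistic), p_value = ht$p.value)
}
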