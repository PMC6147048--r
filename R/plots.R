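#' @rdname plot_occurrence
#' @param object A `mo_occurrence` table.
#' @param ... Unused.
#' @export
autoplot.mo_occurrence <- function(object, ...) {
  df <- as_tibble(object)
  xcol <- if ("family" %in% names(df)) "family" else "group"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[xcol]], y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% of organisms") +
    ggplot2::theme_minimal()
  if ("kingdom" %in% names(df) && xcol != "kingdom") {
    p <- p + ggplot2::facet_wrap(~kingdom)
  }
  p
}

#' Plot an occurrence summary
#'
#' Bar chart of per-group occurrence percentages.
#'
#' @param occurrence A `mo_occurrence` table from [occurrence_summary()] or
#'   [family_occurrence()].
#' @return A ggplot object.
#' @export
plot_occurrence <- function(occurrence) {
  autoplot(occurrence)
}

#' @rdname plot_factor_table
#' @param object A `mo_factor_table`.
#' @param ... Unused.
#' @export
autoplot.mo_factor_table <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$category,
                                                      -.data$percent),
                                   y = .data$percent)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lower,
                                        ymax = .data$ci_upper),
                           width = 0.2) +
    ggplot2::labs(x = attr(object, "factor"),
                  y = sprintf("%% with %s", attr(object, "feature"))) +
    ggplot2::theme_minimal()
}

#' Plot a trait-by-environment table
#'
#' Bar chart with exact binomial confidence intervals per factor category.
#'
#' @param factor_table A [trait_by_factor()] table.
#' @return A ggplot object.
#' @export
plot_factor_table <- function(factor_table) {
  autoplot(factor_table)
}

#' @rdname plot_proteome_sizes
#' @param object A `mo_proteomes` table.
#' @param ... Unused.
#' @export
autoplot.mo_proteomes <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_molybdoproteins)) +
    ggplot2::geom_histogram(binwidth = 2, fill = "seagreen",
                            colour = "white") +
    ggplot2::facet_wrap(~kingdom, scales = "free_y") +
    ggplot2::labs(x = "molybdoproteome size (genes)", y = "organisms") +
    ggplot2::theme_minimal()
}

#' Plot molybdoproteome size distributions
#'
#' Per-kingdom histogram of molybdoprotein gene counts.
#'
#' @param proteomes A [proteome_sizes()] table.
#' @return A ggplot object.
#' @export
plot_proteome_sizes <- function(proteomes) {
  autoplot(proteomes)
}

#' @rdname plot_overlap
#' @param object A `mo_overlap` table.
#' @param ... Unused.
#' @export
autoplot.mo_overlap <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$region,
                                                      -.data$count),
                                   y = .data$count)) +
    ggplot2::geom_col(fill = "mediumpurple") +
    ggplot2::labs(x = "transporter combination", y = "organisms") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a transporter overlap table
#'
#' Region counts of the transporter Venn decomposition.
#'
#' @param overlap A [transporter_overlap()] table.
#' @return A ggplot object.
#' @export
plot_overlap <- function(overlap) {
  autoplot(overlap)
}
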