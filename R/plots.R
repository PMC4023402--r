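#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the estimated stoichiometry landscape
#'
#' Histogram of estimated upper bounds on a log10 scale, filled by
#' sensitivity class; AcP-insensitive sites (bounded only as > 1%) are shown
#' as a rug at 1%.
#'
#' @param object A `stoich_estimates` tibble.
#' @param bins Number of histogram bins (default 40).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stoich_estimates <- function(object, bins = 40, ...) {
  with_bound <- dplyr::filter(object, !is.na(.data$bound_percent))
  ggplot2::ggplot(with_bound,
                  ggplot2::aes(x = .data$bound_percent, fill = .data$sensitivity_class)) +
    ggplot2::geom_histogram(bins = bins, colour = "grey30", linewidth = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "stoichiometry upper bound (%)", y = "sites",
                  fill = "class",
                  title = "Estimated acetylation stoichiometry") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.stoich_estimates
#' @export
autoplot.compartment_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$compartment, y = .data$median_log2_ratio)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "median log2 SILAC ratio",
                  title = "Compartment acetylation dynamics") +
    ggplot2::theme_minimal()
}

#' Boxplot of (corrected) SILAC ratios per compartment
#'
#' @param ratios Tibble with `compartment` and `ratio` columns, as passed to
#'   [compartment_summaries()].
#' @return A ggplot object.
#' @export
plot_compartment_ratios <- function(ratios) {
  ratios <- dplyr::filter(tibble::as_tibble(ratios),
                          !is.na(.data$compartment), !is.na(.data$ratio))
  ggplot2::ggplot(ratios,
                  ggplot2::aes(x = .data$compartment, y = log2(.data$ratio))) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3, fill = "grey85") +
    ggplot2::labs(x = NULL, y = "log2 SILAC ratio") +
    ggplot2::theme_minimal()
}
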