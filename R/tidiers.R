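#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods for stoichiometry estimates
#'
#' `tidy()` summarises a `stoich_estimates` table per sensitivity class
#' (site count, median ratio or minimum ratio, median bound); `glance()`
#' gives a one-row overview: total sites, per-class counts, the detection
#' limit used, and the fraction of sites bounded below 1%.
#'
#' @param x A `stoich_estimates` tibble from [estimate_stoichiometry()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.stoich_estimates <- function(x, ...) {
  x |>
    dplyr::group_by(sensitivity_class = .data$sensitivity_class) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      median_ratio = stats::median(.data$ratio, na.rm = TRUE),
      median_min_ratio = stats::median(.data$min_ratio, na.rm = TRUE),
      median_bound_percent = stats::median(.data$bound_percent, na.rm = TRUE),
      .groups = "drop"
    )
}

#' @rdname tidy.stoich_estimates
#' @export
glance.stoich_estimates <- function(x, ...) {
  limit <- attr(x, "detection_limit")
  classes <- table(factor(x$sensitivity_class,
                          levels = c("sensitive", "insensitive", "no_ratio")))
  below1 <- stoichiometry_fractions(x, thresholds = 1)
  tibble::tibble(
    n_sites = nrow(x),
    n_sensitive = as.integer(classes[["sensitive"]]),
    n_insensitive = as.integer(classes[["insensitive"]]),
    n_no_ratio = as.integer(classes[["no_ratio"]]),
    c_max = attr(x, "c_max") %||% NA_real_,
    detection_limit = if (is.null(limit)) NA_real_ else limit$value,
    fraction_below_1pct = below1$fraction
  )
}

#' Tidy and glance methods for compartment summaries
#'
#' @param x A `compartment_summary` tibble from [compartment_summaries()].
#' @param ... Unused.
#' @return `tidy()` returns the summary as a plain tibble; `glance()` a
#'   one-row overview with the reference compartment and the smallest
#'   Wilcoxon p-value.
#' @export
tidy.compartment_summary <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "compartment_summary")
  out
}

#' @rdname tidy.compartment_summary
#' @export
glance.compartment_summary <- function(x, ...) {
  tibble::tibble(
    n_compartments = nrow(x),
    reference = attr(x, "reference") %||% NA_character_,
    n_sites_total = sum(x$n_sites),
    min_p_vs_reference = suppressWarnings(min(x$p_vs_reference, na.rm = TRUE))
  )
}
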