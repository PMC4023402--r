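#' Write and re-read stoichiometry estimate tables
#'
#' Estimates are serialized as a tab-separated table with a fixed column
#' order (`protein_id`, `position`, `peptide`, `ratio`, `min_ratio`,
#' `sensitivity_class`, `bound_percent`, `flag`, `i_over_ibaq_a`). Missing
#' values are written as empty fields, never sentinel numbers, and the
#' write/read pair is the identity on valid tables up to numeric print
#' precision.
#'
#' @param estimates A tibble of estimates as produced by
#'   [estimate_stoichiometry()].
#' @param path Output (or input) file path.
#' @return `write_estimates()` returns `path` invisibly; `read_estimates()`
#'   returns the estimates tibble.
#' @export
write_estimates <- function(estimates, path) {
  cols <- c("protein_id", "position", "peptide", "ratio", "min_ratio",
            "sensitivity_class", "bound_percent", "flag", "i_over_ibaq_a")
  missing <- setdiff(cols, names(estimates))
  if (length(missing) > 0) {
    abort_format(sprintf("estimates table lacks column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  out <- estimates[cols]
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path), class = "acstoich_io_error")
  }
  readr::read_tsv(
    path,
    col_types = readr::cols(
      protein_id = readr::col_character(),
      position = readr::col_integer(),
      peptide = readr::col_character(),
      ratio = readr::col_double(),
      min_ratio = readr::col_double(),
      sensitivity_class = readr::col_character(),
      bound_percent = readr::col_double(),
      flag = readr::col_character(),
      i_over_ibaq_a = readr::col_double()
    ),
    na = "", progress = FALSE
  )
}
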