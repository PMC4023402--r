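#' Published AQUA reference measurements for Pgk1 and Fas2
#'
#' Eight acetylation sites on yeast 3-phosphoglycerate kinase (Pgk1) and
#' fatty acid synthetase (Fas2) whose absolute stoichiometry after 100 mM
#' AcP treatment was measured against heavy-labeled peptide standards,
#' together with each site's SILAC fold increase and the published initial
#' stoichiometry and degree of chemical acetylation. These measurements
#' anchor the upper-bound method: sensitivity and occupancy are strongly
#' anti-correlated, and the chemical degree has median 0.07% (range
#' 0.01-0.11%). Six of the eight rows round-trip exactly from the printed
#' `s_acp` and `ratio` values; the published values for the other two were
#' derived from unrounded instrument readings, so recomputation differs in
#' the last printed digit (`self_consistent` marks the six).
#'
#' @return Tibble with columns `protein`, `peptide`, `s_acp` (percent,
#'   100 mM AcP), `ratio` (SILAC L/H), `s0_published` (percent),
#'   `degree_published` (percent), `self_consistent`.
#' @export
aqua_reference_sites <- function() {
  path <- system.file("extdata", "pgk1_fas2_aqua.tsv", package = "acstoich",
                      mustWork = TRUE)
  out <- readr::read_tsv(path, col_types = "ccdddd", progress = FALSE)
  dplyr::mutate(out, self_consistent =
    round_half_up(.data$s_acp / .data$ratio, 4) == .data$s0_published)
}

#' Table-style AQUA stoichiometry report
#'
#' Combines measured AcP-treated stoichiometries with SILAC fold increases
#' into the standard report: initial stoichiometry `s0 = s_acp / ratio` and
#' degree of chemical acetylation `c = s_acp - s0`. Internal values stay at
#' full precision; the report columns mirror print precision
#' (4 decimals for stoichiometries, 2 for the degree, half-up), with the
#' degree differenced against the *printed* initial stoichiometry so the
#' report is internally consistent at its own precision.
#'
#' @param aqua Tibble with columns `peptide`, `s_acp` (percent) and `ratio`
#'   (SILAC L/H, >= 1). Output of [aqua_stoichiometry()] joined to site
#'   ratios works directly.
#' @return The input with added columns `s0` (full precision), `degree`
#'   (full precision), `s0_report`, `degree_report`.
#' @export
aqua_report <- function(aqua) {
  aqua <- tibble::as_tibble(aqua)
  missing <- setdiff(c("peptide", "s_acp", "ratio"), names(aqua))
  if (length(missing) > 0) {
    abort_format(sprintf("AQUA report input lacks column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  aqua |>
    dplyr::mutate(
      s0 = initial_stoichiometry(.data$s_acp, .data$ratio),
      degree = chemical_acetylation_degree(.data$s_acp, .data$s0),
      s0_report = round_half_up(.data$s0, 4),
      degree_report = round_half_up(
        chemical_acetylation_degree(.data$s_acp, .data$s0_report), 2)
    )
}
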