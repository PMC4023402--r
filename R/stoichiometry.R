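#' Upper-bound acetylation stoichiometry from AcP-sensitivity
#'
#' Partial chemical acetylation with acetyl-phosphate (AcP) increases the
#' acetylated-peptide signal most where initial occupancy is lowest. Under the
#' conservative assumption that AcP added at most `c_max` percent occupancy at
#' any lysine, a site whose acetylated peptide increased `ratio`-fold
#' (SILAC light/heavy, treated/untreated) had an initial stoichiometry below
#' `c_max / ratio` percent: a 10-fold increase bounds the site below 0.1%, a
#' 20-fold increase below 0.05%. The bound is an explicit "less than" value —
#' division by R rather than the exact algebra c/(R-1) keeps it conservative
#' for all R >= 1.
#'
#' @param ratio SILAC ratio(s) L/H, treated over untreated; must be >= 1
#'   (the bound is undefined for decreased acetylation).
#' @param c_max Assumed maximum degree of chemical acetylation, in percent
#'   (default 1).
#' @return Upper bound(s) on initial stoichiometry, in percent.
#' @examples
#' stoichiometry_upper_bound(10) # 0.1
#' stoichiometry_upper_bound(20) # 0.05
#' @export
stoichiometry_upper_bound <- function(ratio, c_max = 1.0) {
  check_positive(c_max, "c_max")
  if (any(!is.finite(ratio) | ratio < 1)) {
    abort_domain("`ratio` must be >= 1: the bound is undefined for decreased acetylation")
  }
  c_max / ratio
}

# internal: scalar AQUA stoichiometry from light/standard intensity pairs
aqua_stoich_one <- function(ac_light, ac_std, unmod_light, unmod_std,
                            ac_spike, unmod_spike) {
  amount_ac <- (ac_light / ac_std) * ac_spike
  amount_unmod <- (unmod_light / unmod_std) * unmod_spike
  100 * amount_ac / (amount_ac + amount_unmod)
}

#' Absolute stoichiometry from AQUA heavy-standard comparisons
#'
#' Acetylated and unmodified ("corresponding") peptide intensities are each
#' compared to a spiked heavy-labeled standard of known amount; the molar
#' amounts `(light/standard) * spike` then give the occupancy directly as
#' `100 * ac / (ac + unmod)` percent.
#'
#' @param aqua A data frame with columns `peptide`, `ac_light_intensity`,
#'   `ac_standard_intensity`, `unmod_light_intensity`,
#'   `unmod_standard_intensity`, `ac_spike_amount`, `unmod_spike_amount`
#'   (all intensities and spike amounts strictly positive).
#' @return The input as a tibble with an added `s_acp` column, the measured
#'   stoichiometry in percent.
#' @export
aqua_stoichiometry <- function(aqua) {
  aqua <- tibble::as_tibble(aqua)
  num_cols <- c("ac_light_intensity", "ac_standard_intensity",
                "unmod_light_intensity", "unmod_standard_intensity",
                "ac_spike_amount", "unmod_spike_amount")
  missing <- setdiff(num_cols, names(aqua))
  if (length(missing) > 0) {
    abort_format(sprintf("AQUA table lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  for (col in num_cols) {
    if (any(!is.finite(aqua[[col]]) | aqua[[col]] <= 0)) {
      abort_domain(sprintf("all values of '%s' must be strictly positive", col))
    }
  }
  dplyr::mutate(aqua, s_acp = aqua_stoich_one(
    .data$ac_light_intensity, .data$ac_standard_intensity,
    .data$unmod_light_intensity, .data$unmod_standard_intensity,
    .data$ac_spike_amount, .data$unmod_spike_amount
  ))
}

#' Initial stoichiometry and degree of chemical acetylation
#'
#' The occupancy measured after AcP treatment (`s_acp`) divided by the SILAC
#' fold increase (`ratio`) recovers the pre-treatment (initial) occupancy;
#' the difference between treated and initial occupancy is the degree of
#' chemical acetylation contributed by the treatment. Both are computed at
#' full precision; report layers round with [round_half_up()] (4 decimals for
#' stoichiometries, 2 for the chemical degree).
#'
#' @param s_acp Stoichiometry after AcP treatment, percent (> 0).
#' @param ratio SILAC ratio L/H of the treated comparison (>= 1).
#' @param s0 Initial stoichiometry, percent (0 <= s0 <= s_acp).
#' @return Percent values, unrounded.
#' @examples
#' initial_stoichiometry(0.023, 80.8) # ~0.000285, prints as 0.0003
#' chemical_acetylation_degree(0.181, 0.1055) # 0.0755, prints as 0.08
#' @export
initial_stoichiometry <- function(s_acp, ratio) {
  if (any(!is.finite(s_acp) | s_acp <= 0)) abort_domain("`s_acp` must be > 0")
  if (any(!is.finite(ratio) | ratio < 1)) {
    abort_domain("`ratio` must be >= 1: initial stoichiometry is undefined for decreased acetylation")
  }
  s_acp / ratio
}

#' @rdname initial_stoichiometry
#' @export
chemical_acetylation_degree <- function(s_acp, s0) {
  if (any(!is.finite(s_acp) | !is.finite(s0) | s0 < 0)) {
    abort_domain("`s_acp` and `s0` must be finite and `s0` >= 0")
  }
  if (any(s0 > s_acp)) {
    abort_domain("`s0` must not exceed `s_acp`: chemical acetylation cannot be negative")
  }
  s_acp - s0
}

#' Empirical detection limit from heavy-channel peptide intensities
#'
#' Sites without a heavy (untreated) signal still allow a conservative lower
#' bound on their fold increase: the observed heavy-labeled peptide
#' intensities are ranked and the median of the bottom fraction (default 10%)
#' defines an empirical intensity floor. The bottom set size is
#' `max(1, floor(bottom_fraction * n))`.
#'
#' @param heavy_intensities Numeric vector of observed heavy-channel peptide
#'   intensities (all > 0, at least 10 values).
#' @param bottom_fraction Fraction of lowest-intensity peptides whose median
#'   defines the limit (default 0.10).
#' @return A `detection_limit` object with fields `value`, `n_peptides_used`
#'   and `bottom_fraction`.
#' @examples
#' detection_limit(1:100)$value # 5.5
#' @export
detection_limit <- function(heavy_intensities, bottom_fraction = 0.10) {
  if (length(heavy_intensities) < 10) {
    abort_domain("at least 10 heavy-channel intensities are required to estimate a detection limit",
                 class = "acstoich_insufficient_data")
  }
  if (any(!is.finite(heavy_intensities) | heavy_intensities <= 0)) {
    abort_domain("all heavy-channel intensities must be > 0")
  }
  if (!is.numeric(bottom_fraction) || bottom_fraction <= 0 || bottom_fraction > 1) {
    abort_domain("`bottom_fraction` must be in (0, 1]")
  }
  sorted <- sort(heavy_intensities)
  m <- max(1L, floor(bottom_fraction * length(sorted)))
  structure(
    list(value = stats::median(sorted[seq_len(m)]),
         n_peptides_used = m,
         bottom_fraction = bottom_fraction),
    class = "detection_limit"
  )
}

#' @export
print.detection_limit <- function(x, ...) {
  cat(sprintf("Detection limit: %.6g (median of the bottom %d peptides, fraction %.2f)\n",
              x$value, x$n_peptides_used, x$bottom_fraction))
  invisible(x)
}

#' Minimum fold increase for sites without a heavy signal
#'
#' For a site whose untreated (heavy) peptide fell below detection, the
#' treated (light) intensity divided by the detection limit is a conservative
#' lower bound on its true SILAC ratio. Values below 1 are returned
#' unclamped — they indicate generator or input problems rather than a
#' biological signal — with a warning.
#'
#' @param light_intensity Treated-channel intensity (> 0); vectorized.
#' @param limit A [detection_limit()] object or a positive scalar intensity.
#' @return Dimensionless minimum ratio(s).
#' @export
minimum_fold_increase <- function(light_intensity, limit) {
  value <- if (inherits(limit, "detection_limit")) limit$value else limit
  check_positive(value, "limit")
  if (any(!is.finite(light_intensity) | light_intensity <= 0)) {
    abort_domain("`light_intensity` must be > 0")
  }
  out <- light_intensity / value
  if (any(out < 1)) {
    rlang::warn(sprintf("%d minimum ratio(s) below 1: light intensity under the detection limit",
                        sum(out < 1)))
  }
  out
}

#' Count observable tryptic peptides of a protein sequence
#'
#' Fully tryptic in-silico digest (cleavage after K or R, blocked before P,
#' zero missed cleavages); fragments with length inside `[min_len, max_len]`
#' count as observable. This is the denominator of the iBAQ abundance proxy.
#'
#' @param sequence Amino-acid sequence (non-empty).
#' @param min_len,max_len Observable length window (defaults 7 and 30).
#' @return Integer count of observable peptides.
#' @examples
#' count_observable_peptides("AAAAAAKRRRRRRR") # 1
#' count_observable_peptides("MKPK") # 0 (K-P cleavage blocked)
#' @export
count_observable_peptides <- function(sequence, min_len = 7, max_len = 30) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    abort_domain("`sequence` must be a single non-empty amino-acid string")
  }
  fragments <- strsplit(gsub("(?<=[KR])(?!P)", "\x01", sequence, perl = TRUE),
                        "\x01", fixed = TRUE)[[1]]
  lens <- nchar(fragments)
  sum(lens >= min_len & lens <= max_len)
}

#' iBAQ protein abundance and abundance-corrected acetyl intensity
#'
#' `ibaq()` divides a protein's summed peptide intensity by its number of
#' theoretically observable tryptic peptides, a proxy for molar abundance.
#' `i_over_ibaq_a()` divides an acetylated peptide's untreated-channel
#' intensity by the protein's iBAQ, giving an abundance-corrected acetylation
#' score (I/iBAQ-A) that tracks occupancy independently of the AcP assay.
#'
#' @param total_intensity Summed protein intensity (>= 0); vectorized.
#' @param n_observable Number of observable tryptic peptides (>= 1).
#' @param ac_peptide_intensity Acetylated-peptide intensity from the
#'   untreated channel.
#' @param protein_ibaq iBAQ abundance of the host protein; `NA` propagates
#'   (score absent, not zero).
#' @return `ibaq()`: intensity per peptide; `i_over_ibaq_a()`: dimensionless
#'   score.
#' @export
ibaq <- function(total_intensity, n_observable) {
  if (any(!is.finite(total_intensity) | total_intensity < 0)) {
    abort_domain("`total_intensity` must be >= 0")
  }
  if (any(!is.finite(n_observable) | n_observable < 1)) {
    abort_domain("`n_observable` must be >= 1 (proteins without observable peptides are excluded)")
  }
  total_intensity / n_observable
}

#' @rdname ibaq
#' @export
i_over_ibaq_a <- function(ac_peptide_intensity, protein_ibaq) {
  if (any(!is.na(protein_ibaq) & protein_ibaq <= 0)) {
    abort_domain("`protein_ibaq` must be > 0 where present")
  }
  ifelse(is.na(protein_ibaq) | is.na(ac_peptide_intensity),
         NA_real_, ac_peptide_intensity / protein_ibaq)
}

#' Classify sites by AcP-sensitivity
#'
#' Sites whose acetylation rose less than 2-fold after AcP treatment are
#' AcP-insensitive (high initial stoichiometry, estimated only as > 1%);
#' sites with ratio >= 2 are AcP-sensitive; sites without a ratio (heavy
#' channel below detection) form their own class.
#'
#' @param ratio SILAC ratio(s) L/H or `NA`.
#' @return Character vector over `"insensitive"`, `"sensitive"`, `"no_ratio"`.
#' @export
classify_sensitivity <- function(ratio) {
  dplyr::case_when(
    is.na(ratio) ~ "no_ratio",
    ratio < 2 ~ "insensitive",
    TRUE ~ "sensitive"
  )
}

#' Estimate stoichiometry bounds for a full site table
#'
#' Applies the upper-bound estimator to every (optionally naturally
#' occurring) acetylation site: sites with a SILAC ratio >= 2 get the bound
#' `c_max / ratio`; AcP-insensitive sites (ratio < 2) are flagged `">1%"`
#' with no numeric bound; sites without a ratio get a minimum fold increase
#' against the detection limit and the bound `c_max / min_ratio`. Where the
#' host protein carries an iBAQ value, the untreated-channel (heavy)
#' acetyl-peptide intensity yields the I/iBAQ-A score.
#'
#' @param sites Site table as from [read_site_table()].
#' @param proteins Protein table as from [read_protein_table()]; may be
#'   `NULL`, in which case no I/iBAQ-A scores are attached.
#' @param limit A [detection_limit()] computed from the same experiment's
#'   heavy-channel peptide intensities.
#' @param c_max Assumed maximum chemical acetylation, percent (default 1).
#' @param natural_only Keep only sites marked naturally occurring
#'   (default `TRUE`).
#' @return A `stoich_estimates` tibble with columns `protein_id`, `position`,
#'   `peptide`, `ratio`, `min_ratio`, `sensitivity_class`, `bound_percent`,
#'   `flag`, `i_over_ibaq_a`.
#' @export
estimate_stoichiometry <- function(sites, proteins = NULL, limit,
                                   c_max = 1.0, natural_only = TRUE) {
  check_positive(c_max, "c_max")
  if (!inherits(limit, "detection_limit")) {
    abort_domain("`limit` must be a detection_limit object (see detection_limit())")
  }
  sites <- tibble::as_tibble(sites)
  if (natural_only && "naturally_occurring" %in% names(sites)) {
    sites <- dplyr::filter(sites, .data$naturally_occurring)
  }

  est <- dplyr::mutate(sites,
    sensitivity_class = classify_sensitivity(.data$silac_ratio),
    ratio = .data$silac_ratio
  )
  no_ratio <- is.na(est$ratio)
  est$min_ratio <- NA_real_
  if (any(no_ratio)) {
    est$min_ratio[no_ratio] <-
      minimum_fold_increase(est$light_intensity[no_ratio], limit)
  }
  est <- dplyr::mutate(est,
    bound_percent = dplyr::case_when(
      .data$sensitivity_class == "sensitive" ~ c_max / .data$ratio,
      .data$sensitivity_class == "no_ratio" ~ c_max / .data$min_ratio,
      TRUE ~ NA_real_
    ),
    flag = dplyr::case_when(
      .data$sensitivity_class == "insensitive" ~ ">1%",
      .data$sensitivity_class == "no_ratio" & .data$min_ratio < 1 ~ "min_ratio<1",
      TRUE ~ NA_character_
    )
  )

  if (!is.null(proteins)) {
    prot <- dplyr::select(tibble::as_tibble(proteins), "protein_id", "ibaq")
    est <- dplyr::left_join(est, prot, by = "protein_id")
    est$i_over_ibaq_a <- i_over_ibaq_a(est$heavy_intensity, est$ibaq)
    est$ibaq <- NULL
  } else {
    est$i_over_ibaq_a <- NA_real_
  }

  out <- dplyr::select(est, "protein_id", "position", "peptide", "ratio",
                       "min_ratio", "sensitivity_class", "bound_percent",
                       "flag", "i_over_ibaq_a")
  class(out) <- c("stoich_estimates", class(out))
  attr(out, "c_max") <- c_max
  attr(out, "detection_limit") <- limit
  out
}

#' Cumulative fractions of sites below stoichiometry thresholds
#'
#' For each threshold `t`, the fraction of estimated sites with an upper
#' bound strictly below `t` percent. Sites flagged `">1%"` (AcP-insensitive)
#' have unknown occupancy above 1% and are counted in every denominator but
#' no numerator.
#'
#' @param estimates A `stoich_estimates` tibble.
#' @param thresholds Stoichiometry thresholds in percent
#'   (default `c(0.02, 0.05, 0.1, 1)`).
#' @return Tibble with columns `threshold`, `n_below`, `fraction`.
#' @export
stoichiometry_fractions <- function(estimates, thresholds = c(0.02, 0.05, 0.1, 1)) {
  if (nrow(estimates) == 0) abort_domain("no estimates supplied")
  flagged <- !is.na(estimates$flag) & estimates$flag == ">1%"
  bounds <- estimates$bound_percent
  n_total <- nrow(estimates)
  purrr::map_dfr(thresholds, function(t) {
    n_below <- sum(!flagged & !is.na(bounds) & bounds < t)
    tibble::tibble(threshold = t, n_below = n_below, fraction = n_below / n_total)
  })
}
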