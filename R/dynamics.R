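#' Protein-abundance-corrected site ratios
#'
#' A site's SILAC ratio confounds changes in acetylation with changes in the
#' host protein's abundance; dividing by the protein's own SILAC ratio (in
#' linear space) isolates the acetylation change. `correct_site_ratio()` is
#' the scalar/vector kernel; `corrected_site_ratios()` joins a site table to
#' a protein table and flags (rather than silently drops) sites whose protein
#' has no ratio.
#'
#' @param site_ratio,protein_ratio SILAC ratios (> 0).
#' @return `correct_site_ratio()`: corrected ratio(s).
#' @export
correct_site_ratio <- function(site_ratio, protein_ratio) {
  if (any(!is.finite(site_ratio) | site_ratio <= 0) ||
      any(!is.finite(protein_ratio) | protein_ratio <= 0)) {
    abort_domain("both `site_ratio` and `protein_ratio` must be > 0")
  }
  site_ratio / protein_ratio
}

#' @rdname correct_site_ratio
#' @param sites Site table with `protein_id` and `silac_ratio` columns.
#' @param proteins Protein table with `protein_id` and `silac_ratio` columns.
#' @return `corrected_site_ratios()`: the site table as a tibble with added
#'   `protein_ratio`, `corrected_ratio` and logical `excluded` columns
#'   (`excluded` marks sites lacking a site or protein ratio).
#' @export
corrected_site_ratios <- function(sites, proteins) {
  prot <- dplyr::select(tibble::as_tibble(proteins),
                        "protein_id", protein_ratio = "silac_ratio")
  out <- dplyr::left_join(tibble::as_tibble(sites), prot, by = "protein_id")
  out <- dplyr::mutate(out,
    excluded = is.na(.data$silac_ratio) | is.na(.data$protein_ratio),
    corrected_ratio = ifelse(.data$excluded, NA_real_,
                             .data$silac_ratio / .data$protein_ratio)
  )
  n_excl <- sum(out$excluded)
  if (n_excl > 0) {
    rlang::inform(sprintf(
      "%d site(s) excluded from corrected analyses (missing site or protein ratio)", n_excl))
  }
  out
}

#' Exclusive subcellular localization
#'
#' A protein counts toward a compartment's acetylation distribution only when
#' it localizes exclusively to one of the three tracked compartments
#' (mitochondrion, cytoplasm, nucleus); multi-localized or unlocalized
#' proteins return `NA`.
#'
#' @param localizations Character vector of semicolon-separated compartment
#'   labels (one element per protein), e.g. `"mitochondrion;nucleus"`.
#' @return Character vector: the exclusive compartment or `NA`.
#' @export
exclusive_localization <- function(localizations) {
  tracked <- c("mitochondrion", "cytoplasm", "nucleus")
  vapply(localizations, function(x) {
    labs <- unique(parse_localizations(x))
    if (length(labs) == 1L && labs %in% tracked) labs else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided rank-sum p-value comparing two independent groups (compartment
#' ratio distributions are independent site sets). Exact enumeration is used
#' when the smaller group has at most 8 observations and there are no ties;
#' otherwise the normal approximation with midranks, tie-corrected variance
#' and continuity correction.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    abort_domain("both groups must be non-empty")
  }
  ties <- any(duplicated(c(a, b)))
  exact <- min(length(a), length(b)) <= 8 && !ties
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value
  )
}

#' One-sided Fisher enrichment probability
#'
#' Hypergeometric upper-tail probability that a selection of `n` proteins
#' contains `k` or more carrying a term, given `K` carriers among `N`
#' background proteins. One-sided (enrichment) by design, matching the
#' term-enrichment question.
#'
#' @param k Carriers observed in the selection.
#' @param n Selection size.
#' @param K Carriers in the background.
#' @param N Background size.
#' @return P(X >= k) under the hypergeometric null.
#' @export
fisher_enrichment <- function(k, n, K, N) {
  ok <- k >= 0 & n >= 0 & K >= 0 & k <= n & n <= N & k <= K & K <= N
  if (any(!ok)) abort_domain("inconsistent counts: need 0 <= k <= min(n, K) and n, K <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term enrichment across an annotation map
#'
#' Tests every annotation term for enrichment in a protein selection against
#' a background, via [fisher_enrichment()]. Raw p-values are reported
#' alongside Benjamini-Hochberg adjusted values; the correction is this
#' package's choice of multiplicity control, recorded in the
#' `"p_adjust_method"` attribute of the result.
#'
#' @param selection Character vector of selected protein ids.
#' @param background Character vector of background protein ids (must contain
#'   the selection).
#' @param annotation Long-form annotation tibble (`protein_id`, `term`) as
#'   from [read_annotation_table()].
#' @return Tibble with columns `term`, `k`, `n`, `K`, `N`, `p`, `p_bh`,
#'   sorted by `p`.
#' @export
term_enrichment <- function(selection, background, annotation) {
  selection <- unique(selection)
  background <- unique(background)
  if (!all(selection %in% background)) {
    abort_domain("`selection` must be a subset of `background`")
  }
  ann <- dplyr::filter(tibble::as_tibble(annotation),
                       .data$protein_id %in% background)
  ann <- dplyr::distinct(ann, .data$protein_id, .data$term)
  n <- length(selection)
  N <- length(background)
  out <- ann |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      K = dplyr::n(),
      k = sum(.data$protein_id %in% selection),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n = n, N = N,
      p = fisher_enrichment(.data$k, n, .data$K, N),
      p_bh = stats::p.adjust(.data$p, method = "BH")
    ) |>
    dplyr::select("term", "k", "n", "K", "N", "p", "p_bh") |>
    dplyr::arrange(.data$p)
  attr(out, "p_adjust_method") <- "BH"
  out
}

#' Fraction of ratios above a fold threshold
#'
#' @param ratios Non-empty numeric vector of (positive) fold changes.
#' @param fold Fold threshold; strictly-greater comparison.
#' @return Proportion of `ratios` exceeding `fold`.
#' @export
fraction_above <- function(ratios, fold) {
  if (length(ratios) == 0) abort_domain("`ratios` must be non-empty")
  mean(ratios > fold)
}

#' Corresponding-peptide abundance check
#'
#' Partial chemical acetylation should leave unmodified counterpart
#' ("corresponding") peptides essentially unchanged; a median near 1 and a
#' high fraction of treated/untreated ratios within 2-fold of 1 evidence
#' that the treatment modified only a small fraction of each protein's
#' copies.
#'
#' @param unmod_ratios Non-empty vector of corresponding-peptide
#'   treated/untreated ratios.
#' @return Tibble with `n`, `median_ratio`, `fraction_within_2fold`.
#' @export
cp_abundance_check <- function(unmod_ratios) {
  if (length(unmod_ratios) == 0) abort_domain("`unmod_ratios` must be non-empty")
  tibble::tibble(
    n = length(unmod_ratios),
    median_ratio = stats::median(unmod_ratios),
    fraction_within_2fold = mean(unmod_ratios >= 0.5 & unmod_ratios <= 2)
  )
}

#' Filter TMT records by parent-ion purity
#'
#' Reporter-ion quantification is unreliable when co-isolated peptides
#' contribute to the MS/MS spectrum; records are retained when the targeted
#' parent ion constituted at least `threshold` of the total ion current
#' (inclusive at the threshold). Record contents are never altered, only
#' membership.
#'
#' @param records TMT tibble with a `parent_purity` column.
#' @param threshold Minimum purity fraction (default 0.90).
#' @return The retained rows.
#' @export
tmt_purity_filter <- function(records, threshold = 0.90) {
  dplyr::filter(tibble::as_tibble(records), .data$parent_purity >= threshold)
}

#' TMT relative abundance with equal-variance t-test
#'
#' Mean reporter intensity of the treated channels over the control
#' channels, with a two-tailed pooled-variance t-test. Groups with zero
#' pooled variance cannot support a t statistic; they return a flagged
#' degenerate result (p = 0 when the means differ, p = 1 when identical).
#'
#' @param treated,control Numeric vectors of replicate reporter intensities
#'   (each with >= 2 values for a p-value).
#' @return Tibble with `ratio`, `p_value`, `flag` (`NA`, `"degenerate"`, or
#'   `"no_p_value"`).
#' @export
tmt_relative_abundance <- function(treated, control) {
  ratio <- mean(treated) / mean(control)
  if (length(treated) < 2 || length(control) < 2) {
    return(tibble::tibble(ratio = ratio, p_value = NA_real_, flag = "no_p_value"))
  }
  pooled_var <- (sum((treated - mean(treated))^2) + sum((control - mean(control))^2)) /
    (length(treated) + length(control) - 2)
  if (pooled_var == 0) {
    p <- if (isTRUE(all.equal(mean(treated), mean(control)))) 1 else 0
    return(tibble::tibble(ratio = ratio, p_value = p, flag = "degenerate"))
  }
  p <- stats::t.test(treated, control, var.equal = TRUE)$p.value
  tibble::tibble(ratio = ratio, p_value = p, flag = NA_character_)
}

#' Mitochondrial acetyl-CoA pool arithmetic
#'
#' If loss of the pyruvate dehydrogenase subunit (pda1) removes the
#' mitochondrial acetyl-CoA pool, then the drop from wild-type to pda1-null
#' total acetyl-CoA measures that pool, and the same subtraction in a
#' citrate-synthase-null (cit1) background measures its enlarged pool;
#' their quotient is the mitochondrial pool fold change.
#'
#' @param total_wt,total_pda1,total_cit1 Total acetyl-CoA per cell
#'   equivalent in wild-type, pda1-null and cit1-null cells; requires
#'   `total_wt > total_pda1` and `total_cit1 > total_pda1`.
#' @return Fold change of the mitochondrial pool (cit1-null over wild-type).
#' @examples
#' mito_pool_fold_change(3, 2, 3.9) # 1.9
#' @export
mito_pool_fold_change <- function(total_wt, total_pda1, total_cit1) {
  check_positive(total_wt, "total_wt"); check_positive(total_pda1, "total_pda1")
  check_positive(total_cit1, "total_cit1")
  if (total_wt <= total_pda1 || total_cit1 <= total_pda1) {
    abort_domain("pool differences must be positive: need total_wt > total_pda1 and total_cit1 > total_pda1")
  }
  (total_cit1 - total_pda1) / (total_wt - total_pda1)
}

#' In-compartment vs out-of-compartment concentration ratio
#'
#' A compartment holding fraction `pool_fraction` of a metabolite in
#' fraction `volume_fraction` of the cell volume has a concentration
#' `(p/v) / ((1-p)/(1-v))`-fold higher than the rest of the cell. A
#' mitochondrial acetyl-CoA pool of one third in 1.5-2% of the cell volume
#' implies a 20-30-fold higher mitochondrial concentration.
#'
#' @param pool_fraction Fraction of the metabolite pool in the compartment
#'   (0 < p < 1).
#' @param volume_fraction Fraction of cell volume occupied (0 < v < 1).
#' @return Dimensionless concentration fold.
#' @export
compartment_concentration_fold <- function(pool_fraction, volume_fraction) {
  if (any(pool_fraction <= 0 | pool_fraction >= 1) ||
      any(volume_fraction <= 0 | volume_fraction >= 1)) {
    abort_domain("`pool_fraction` and `volume_fraction` must be strictly between 0 and 1")
  }
  (pool_fraction / volume_fraction) / ((1 - pool_fraction) / (1 - volume_fraction))
}

#' Compartment-resolved ratio summaries
#'
#' Median log2 and linear SILAC ratios per subcellular compartment, with a
#' Wilcoxon rank-sum p-value against a named reference compartment (computed
#' on log2 ratios; the test is rank-based, so the scale only aids
#' reporting). Medians commute with monotone transforms, so
#' `median_linear_ratio = 2 ^ median_log2_ratio` holds exactly. Compartments
#' with no sites are omitted with a notice.
#'
#' @param ratios Tibble with columns `compartment` and `ratio` (linear,
#'   typically protein-corrected site ratios), one row per site.
#' @param reference Compartment compared against (default `"cytoplasm"`).
#' @return A `compartment_summary` tibble with columns `compartment`,
#'   `n_sites`, `median_log2_ratio`, `median_linear_ratio`,
#'   `p_vs_reference`.
#' @export
compartment_summaries <- function(ratios, reference = "cytoplasm") {
  ratios <- dplyr::filter(tibble::as_tibble(ratios),
                          !is.na(.data$compartment), !is.na(.data$ratio))
  if (nrow(ratios) == 0) abort_domain("no sites with both compartment and ratio")
  present <- unique(ratios$compartment)
  absent <- setdiff(COMPARTMENTS[COMPARTMENTS != "other"], present)
  if (length(absent) > 0) {
    rlang::inform(sprintf("no sites in compartment(s): %s",
                          paste(absent, collapse = ", ")))
  }
  if (!reference %in% present) {
    abort_domain(sprintf("reference compartment '%s' has no sites", reference))
  }
  ref_log2 <- log2(ratios$ratio[ratios$compartment == reference])
  out <- ratios |>
    dplyr::group_by(.data$compartment) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      median_linear_ratio = stats::median(.data$ratio),
      p_vs_reference = if (.data$compartment[1] == reference) NA_real_ else
        wilcoxon_rank_sum(log2(.data$ratio), ref_log2),
      .groups = "drop"
    ) |>
    dplyr::mutate(median_log2_ratio = log2(.data$median_linear_ratio)) |>
    dplyr::select("compartment", "n_sites", "median_log2_ratio",
                  "median_linear_ratio", "p_vs_reference")
  class(out) <- c("compartment_summary", class(out))
  attr(out, "reference") <- reference
  out
}
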