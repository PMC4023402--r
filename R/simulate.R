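#' Configuration for the synthetic SILAC acetylation generator
#'
#' The generator emulates the statistical structure of processed
#' site/protein quantification tables from a partial-chemical-acetylation
#' SILAC experiment: log-normal protein abundance; a site-occupancy mixture
#' dominated by very low stoichiometries with a high-stoichiometry nuclear
#' subpopulation; per-lysine chemical reactivity scattered around a median
#' of 0.07% (the measured 0.01-0.11% range); a higher basal acetylation
#' level in mitochondria than cytoplasm; multiplicative intensity noise; and
#' intensity-based censoring of the heavy (untreated) channel. It does not
#' simulate spectra, chromatography or identification error.
#'
#' @param n_proteins Number of proteins (default 300).
#' @param abundance_meanlog,abundance_sdlog Log-normal protein copy-number
#'   parameters (defaults `log(1e9)` and 1.5, spanning the several orders of
#'   magnitude typical of iBAQ abundances).
#' @param compartment_probs Named probabilities over
#'   mitochondrion/cytoplasm/nucleus/other; must sum to 1.
#' @param sites_per_protein Poisson mean of acetylation sites per protein
#'   (default 2).
#' @param low_stoich_range Percent interval sampled log-uniformly for
#'   low-stoichiometry sites (default `c(1e-4, 1e-1)`).
#' @param high_stoich_fraction_nuclear Fraction of nuclear sites drawn from
#'   the high-stoichiometry range (default 0.20, putting ~95% of all sites
#'   below 1%).
#' @param high_stoich_range Percent interval for the high-stoichiometry
#'   nuclear subpopulation (default `c(1, 100)`, log-uniform).
#' @param reactivity_median,reactivity_sdlog Log-normal per-lysine chemical
#'   reactivity in percent (median 0.07, sdlog 0.7), truncated at
#'   `reactivity_max`.
#' @param reactivity_max Upper truncation of reactivity in percent
#'   (default 1).
#' @param compartment_basal_multiplier Named per-compartment factor on
#'   low-range stoichiometries (default mitochondrion 3x).
#' @param noise_cv Coefficient of variation of multiplicative (log-normal)
#'   intensity noise (default 0.2).
#' @param detection_threshold Intensity below which the heavy channel is
#'   censored (default 3e4).
#' @param natural_fraction Probability that a site is marked naturally
#'   occurring (default 0.85).
#' @param seed Integer seed governing all sampling.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_proteins = 300,
                             abundance_meanlog = log(1e9),
                             abundance_sdlog = 1.5,
                             compartment_probs = c(mitochondrion = 0.20,
                                                   cytoplasm = 0.40,
                                                   nucleus = 0.25,
                                                   other = 0.15),
                             sites_per_protein = 2,
                             low_stoich_range = c(1e-4, 1e-1),
                             high_stoich_fraction_nuclear = 0.20,
                             high_stoich_range = c(1, 100),
                             reactivity_median = 0.07,
                             reactivity_sdlog = 0.7,
                             reactivity_max = 1.0,
                             compartment_basal_multiplier = c(mitochondrion = 3,
                                                              cytoplasm = 1,
                                                              nucleus = 1,
                                                              other = 1),
                             noise_cv = 0.2,
                             detection_threshold = 3e4,
                             natural_fraction = 0.85,
                             seed = 1L) {
  cfg <- list(
    n_proteins = n_proteins, abundance_meanlog = abundance_meanlog,
    abundance_sdlog = abundance_sdlog, compartment_probs = compartment_probs,
    sites_per_protein = sites_per_protein, low_stoich_range = low_stoich_range,
    high_stoich_fraction_nuclear = high_stoich_fraction_nuclear,
    high_stoich_range = high_stoich_range, reactivity_median = reactivity_median,
    reactivity_sdlog = reactivity_sdlog, reactivity_max = reactivity_max,
    compartment_basal_multiplier = compartment_basal_multiplier,
    noise_cv = noise_cv, detection_threshold = detection_threshold,
    natural_fraction = natural_fraction, seed = as.integer(seed)
  )
  problems <- character()
  bad <- function(msg) problems <<- c(problems, msg)
  if (!is.numeric(n_proteins) || n_proteins < 1) bad("n_proteins: must be >= 1")
  if (abundance_sdlog < 0) bad("abundance_sdlog: must be >= 0")
  if (!setequal(names(compartment_probs), COMPARTMENTS) ||
      abs(sum(compartment_probs) - 1) > 1e-8 || any(compartment_probs < 0)) {
    bad("compartment_probs: must be non-negative, named over all four compartments, and sum to 1")
  }
  if (sites_per_protein <= 0) bad("sites_per_protein: must be > 0")
  range_ok <- function(r) length(r) == 2 && all(r > 0) && r[1] < r[2]
  if (!range_ok(low_stoich_range)) bad("low_stoich_range: must be a positive increasing pair")
  if (!range_ok(high_stoich_range) || high_stoich_range[2] > 100) {
    bad("high_stoich_range: must be a positive increasing pair with maximum <= 100")
  }
  if (high_stoich_fraction_nuclear < 0 || high_stoich_fraction_nuclear > 1) {
    bad("high_stoich_fraction_nuclear: must be in [0, 1]")
  }
  if (reactivity_median <= 0 || reactivity_sdlog < 0 || reactivity_max <= 0 ||
      reactivity_max > 100 || reactivity_median > reactivity_max) {
    bad("reactivity_model: need 0 < reactivity_median <= reactivity_max <= 100 and reactivity_sdlog >= 0")
  }
  if (!setequal(names(compartment_basal_multiplier), COMPARTMENTS) ||
      any(compartment_basal_multiplier <= 0)) {
    bad("compartment_basal_multiplier: must be positive and named over all four compartments")
  }
  if (noise_cv < 0) bad("noise_cv: must be >= 0")
  if (!is.numeric(detection_threshold) || detection_threshold <= 0) {
    bad("detection_threshold: must be > 0")
  }
  if (natural_fraction < 0 || natural_fraction > 1) bad("natural_fraction: must be in [0, 1]")
  if (length(problems) > 0) {
    rlang::abort(c("invalid generator configuration:", problems),
                 class = "acstoich_config_error")
  }
  structure(cfg, class = "generator_config")
}

# internal: sd of log-intensity from a coefficient of variation
cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

# internal: log-uniform draw
rloguniform <- function(n, range) {
  exp(runif(n, log(range[1]), log(range[2])))
}

# internal: truncated log-normal reactivity draws (percent)
rreactivity <- function(n, median, sdlog, max) {
  out <- rlnorm(n, meanlog = log(median), sdlog = sdlog)
  over <- which(out > max)
  for (i in over) {
    draw <- rlnorm(20, meanlog = log(median), sdlog = sdlog)
    draw <- draw[draw <= max]
    out[i] <- if (length(draw) > 0) draw[1] else max
  }
  out
}

# internal: a synthetic acetyl-peptide string with one "(ac)" marker
random_acetyl_peptide <- function(n) {
  aa <- c("A", "D", "E", "F", "G", "H", "I", "L", "M", "N",
          "P", "Q", "S", "T", "V", "W", "Y")
  vapply(seq_len(n), function(i) {
    pre <- paste(sample(aa, sample(4:8, 1), replace = TRUE), collapse = "")
    post <- paste(sample(aa, sample(3:6, 1), replace = TRUE), collapse = "")
    paste0(pre, "K(ac)", post, sample(c("K", "R"), 1))
  }, character(1))
}

#' Generate a synthetic SILAC acetylation dataset with ground truth
#'
#' Draws a protein table, an acetyl-site table, the heavy-channel intensity
#' list used for the detection limit, and a ground-truth table, under the
#' model: protein abundance `A ~ log-normal`; per-site untreated
#' stoichiometry `s0` from the compartment-weighted low/high mixture;
#' treated stoichiometry `s1 = s0 + c * (1 - s0/100)` where `c` is the
#' per-lysine chemical reactivity applied to the unmodified fraction; heavy
#' intensity proportional to `A * s0` and light to `A * s1`, each with
#' multiplicative log-normal noise; heavy intensities below the detection
#' threshold are censored (reported absent) and flagged in the truth table.
#' Identical seeds give identical output.
#'
#' @param config A [generator_config()].
#' @return A list with elements `sites`, `proteins`, `heavy_intensities`
#'   (observed, uncensored heavy-channel intensities), and `truth`
#'   (`protein_id`, `position`, `compartment`, `true_stoichiometry` = s0,
#'   `reactivity`, `treated_stoichiometry` = s1, `true_ratio` = s1/s0,
#'   `censored_heavy`).
#' @export
generate_dataset <- function(config = generator_config()) {
  if (!inherits(config, "generator_config")) {
    rlang::abort("`config` must be created by generator_config()",
                 class = "acstoich_config_error")
  }
  set.seed(config$seed)
  n_prot <- as.integer(config$n_proteins)
  sdlog_noise <- cv_to_sdlog(config$noise_cv)

  protein_id <- sprintf("SYN%04d", seq_len(n_prot))
  abundance <- rlnorm(n_prot, config$abundance_meanlog, config$abundance_sdlog)
  compartment <- sample(names(config$compartment_probs), n_prot,
                        replace = TRUE, prob = config$compartment_probs)
  n_obs <- 1L + rpois(n_prot, 24)
  # a second, non-exclusive localization for a minority of proteins
  extra <- runif(n_prot) < 0.10
  localizations <- vapply(seq_len(n_prot), function(i) {
    if (extra[i]) {
      second <- sample(setdiff(COMPARTMENTS, compartment[i]), 1)
      paste(c(compartment[i], second), collapse = ";")
    } else compartment[i]
  }, character(1))
  proteins <- tibble::tibble(
    protein_id = protein_id,
    total_intensity = abundance * n_obs * rlnorm(n_prot, 0, sdlog_noise),
    silac_ratio = rlnorm(n_prot, 0, sdlog_noise),
    sequence = NA_character_,
    n_observable_peptides = n_obs,
    localizations = localizations
  )
  proteins$ibaq <- proteins$total_intensity / proteins$n_observable_peptides

  n_sites_per <- rpois(n_prot, config$sites_per_protein)
  site_prot <- rep(seq_len(n_prot), n_sites_per)
  n_sites <- length(site_prot)
  position <- unlist(lapply(n_sites_per[n_sites_per > 0], function(k) {
    sort(sample(500, k))
  }))

  comp <- compartment[site_prot]
  high <- comp == "nucleus" & runif(n_sites) < config$high_stoich_fraction_nuclear
  s0 <- rloguniform(n_sites, config$low_stoich_range) *
    unname(config$compartment_basal_multiplier[comp])
  s0[high] <- rloguniform(sum(high), config$high_stoich_range)
  s0 <- pmin(s0, 100)
  reactivity <- rreactivity(n_sites, config$reactivity_median,
                            config$reactivity_sdlog, config$reactivity_max)
  s1 <- s0 + reactivity * (1 - s0 / 100)

  efficiency <- rlnorm(n_sites, 0, 1)
  heavy_true <- abundance[site_prot] * efficiency * s0 / 100
  light_true <- abundance[site_prot] * efficiency * s1 / 100
  heavy_obs <- heavy_true * rlnorm(n_sites, 0, sdlog_noise)
  light_obs <- light_true * rlnorm(n_sites, 0, sdlog_noise)
  censored <- heavy_obs < config$detection_threshold

  sites <- tibble::tibble(
    protein_id = protein_id[site_prot],
    position = as.integer(position),
    peptide = random_acetyl_peptide(n_sites),
    light_intensity = light_obs,
    heavy_intensity = ifelse(censored, NA_real_, heavy_obs),
    silac_ratio = ifelse(censored, NA_real_, light_obs / heavy_obs),
    naturally_occurring = runif(n_sites) < config$natural_fraction
  )
  truth <- tibble::tibble(
    protein_id = sites$protein_id,
    position = sites$position,
    compartment = unname(comp),
    true_stoichiometry = unname(s0),
    reactivity = reactivity,
    treated_stoichiometry = unname(s1),
    true_ratio = unname(s1 / s0),
    censored_heavy = censored
  )
  list(sites = sites, proteins = proteins,
       heavy_intensities = heavy_obs[!censored], truth = truth)
}

#' Generate a synthetic AQUA fixture from ground truth
#'
#' Builds light/standard intensity pairs for acetylated and unmodified
#' peptides consistent with the true treated stoichiometries of a truth
#' subset: with 100 amount units of protein, `s1` units are acetylated and
#' `100 - s1` unmodified; light intensities are `standard * amount / spike`,
#' everything under multiplicative noise. With zero noise,
#' [aqua_stoichiometry()] inverts the construction exactly.
#'
#' @param truth Truth tibble (or subset) from [generate_dataset()], needing
#'   columns `protein_id`, `position`, `treated_stoichiometry`.
#' @param ac_spike,unmod_spike Heavy-standard spike amounts (defaults 1 and
#'   100 amount units).
#' @param noise_cv Multiplicative intensity noise CV (default 0.05).
#' @param seed Integer seed.
#' @return AQUA tibble (canonical columns plus `protein_id`, `position` and
#'   `true_s_acp`).
#' @export
generate_aqua_fixture <- function(truth, ac_spike = 1, unmod_spike = 100,
                                  noise_cv = 0.05, seed = 1L) {
  truth <- tibble::as_tibble(truth)
  if (nrow(truth) == 0) {
    return(tibble::tibble(
      peptide = character(), protein_id = character(), position = integer(),
      ac_light_intensity = double(), ac_standard_intensity = double(),
      unmod_light_intensity = double(), unmod_standard_intensity = double(),
      ac_spike_amount = double(), unmod_spike_amount = double(),
      true_s_acp = double()
    ))
  }
  set.seed(as.integer(seed))
  n <- nrow(truth)
  sdlog <- cv_to_sdlog(noise_cv)
  s1 <- truth$treated_stoichiometry
  amount_ac <- s1
  amount_unmod <- 100 - s1
  ac_std <- 1e6 * rlnorm(n, 0, sdlog)
  unmod_std <- 1e6 * rlnorm(n, 0, sdlog)
  tibble::tibble(
    peptide = sprintf("%s_K%d", truth$protein_id, truth$position),
    protein_id = truth$protein_id,
    position = truth$position,
    ac_light_intensity = ac_std * (amount_ac / ac_spike) * rlnorm(n, 0, sdlog),
    ac_standard_intensity = ac_std,
    unmod_light_intensity = unmod_std * (amount_unmod / unmod_spike) * rlnorm(n, 0, sdlog),
    unmod_standard_intensity = unmod_std,
    ac_spike_amount = ac_spike,
    unmod_spike_amount = unmod_spike,
    true_s_acp = s1
  )
}

#' Generate a synthetic TMT reporter fixture
#'
#' Emulates a dose-response nonenzymatic-acetylation experiment quantified
#' with isobaric tags: acetylated-peptide reporter channels scale with the
#' per-dose effect, non-acetylated channels stay flat, and parent-ion
#' purities are drawn uniformly from `purity_range` so the 90% purity filter
#' can be exercised.
#'
#' @param n_peptides Number of peptides per class (acetylated and
#'   non-acetylated).
#' @param effects Named numeric vector of fold effects per dose channel,
#'   e.g. `c(dose_100uM = 1.2, dose_1mM = 2, dose_10mM = 3)`.
#' @param purity_range Uniform sampling range of parent-ion purity
#'   (default `c(0.85, 1)`).
#' @param intensity_meanlog,intensity_sdlog Base reporter intensity
#'   distribution (defaults `log(1e6)` and 0.15).
#' @param noise_cv Multiplicative reporter noise CV (default 0.1).
#' @param seed Integer seed.
#' @return Tibble with `peptide`, `is_acetylated`, `parent_purity`,
#'   `reporter_control` and one `reporter_<dose>` column per effect.
#' @export
generate_tmt_fixture <- function(n_peptides = 6,
                                 effects = c(dose_100uM = 1.2, dose_1mM = 2, dose_10mM = 3),
                                 purity_range = c(0.85, 1),
                                 intensity_meanlog = log(1e6),
                                 intensity_sdlog = 0.15,
                                 noise_cv = 0.1,
                                 seed = 1L) {
  if (is.null(names(effects)) || any(!nzchar(names(effects)))) {
    rlang::abort("`effects` must be a named vector (dose -> fold effect)",
                 class = "acstoich_config_error")
  }
  set.seed(as.integer(seed))
  sdlog <- cv_to_sdlog(noise_cv)
  n <- 2L * n_peptides
  is_ac <- rep(c(TRUE, FALSE), each = n_peptides)
  base <- rlnorm(n, intensity_meanlog, intensity_sdlog)
  out <- tibble::tibble(
    peptide = sprintf("TMTPEP%02d", seq_len(n)),
    is_acetylated = is_ac,
    parent_purity = runif(n, purity_range[1], purity_range[2]),
    reporter_control = base * rlnorm(n, 0, sdlog)
  )
  for (dose in names(effects)) {
    fold <- ifelse(is_ac, effects[[dose]], 1)
    out[[paste0("reporter_", dose)]] <- base * fold * rlnorm(n, 0, sdlog)
  }
  out
}
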