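#' Config-driven pipeline runners
#'
#' Each runner wraps one stage of the analysis behind a single configuration
#' list (or YAML file): `run_simulate()` writes a synthetic dataset,
#' `run_stoichiometry()` turns site/protein/heavy-intensity tables into a
#' stoichiometry estimate table plus cumulative fractions,
#' `run_dynamics()` produces protein-corrected compartment summaries and
#' optional term enrichment, and `run_aqua()` produces the absolute
#' stoichiometry report. Every runner writes a machine-readable JSON
#' manifest (inputs, full configuration, seed, config hash) alongside its
#' outputs, sufficient to reproduce them bit-identically. A thin command-line
#' wrapper over these functions ships at
#' `system.file("cli", "acstoich.R", package = "acstoich")`.
#'
#' @param config A named list, or the path to a YAML file holding one.
#'   Recognised keys are documented per runner below; unknown keys are kept
#'   in the manifest but otherwise ignored.
#' @return Each runner returns its main results invisibly (see below) and
#'   writes files under `config$out_dir`.
#' @name pipeline
NULL

# internal: accept a list or a YAML path
load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      rlang::abort(sprintf("config file not found: %s", config),
                   class = "acstoich_io_error")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    rlang::abort("`config` must be a named list or the path to a YAML file",
                 class = "acstoich_config_error")
  }
  config
}

# internal: merge user config over defaults (shallow)
merge_config <- function(defaults, config) {
  utils::modifyList(defaults, config)
}

# internal: require an out_dir, create it, return normalized path
prepare_out_dir <- function(config) {
  out_dir <- config$out_dir
  if (is.null(out_dir)) {
    rlang::abort("config key 'out_dir' is required", class = "acstoich_config_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out_dir
}

# internal: write the reproducibility manifest
write_manifest <- function(out_dir, command, config, inputs = character()) {
  manifest <- list(
    command = command,
    inputs = as.list(inputs),
    config = config,
    seed = config$seed,
    config_hash = rlang::hash(config)
  )
  path <- file.path(out_dir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @describeIn pipeline Generate and write a synthetic dataset. Keys:
#'   `out_dir` (required), `seed` (default 1), `generator` (a list of
#'   [generator_config()] arguments). Writes `sites.tsv`, `proteins.tsv`,
#'   `heavy_intensities.tsv`, `truth.tsv` and the manifest; returns the
#'   dataset list invisibly.
#' @export
run_simulate <- function(config = list()) {
  config <- load_config(config)
  config <- merge_config(list(seed = 1L, generator = list()), config)
  out_dir <- prepare_out_dir(config)
  gen_args <- merge_config(config$generator, list(seed = config$seed))
  gen_cfg <- do.call(generator_config, gen_args)
  dataset <- generate_dataset(gen_cfg)
  readr::write_tsv(dataset$sites, file.path(out_dir, "sites.tsv"), na = "",
                   progress = FALSE)
  readr::write_tsv(dataset$proteins, file.path(out_dir, "proteins.tsv"), na = "",
                   progress = FALSE)
  readr::write_tsv(tibble::tibble(heavy_intensity = dataset$heavy_intensities),
                   file.path(out_dir, "heavy_intensities.tsv"), progress = FALSE)
  readr::write_tsv(dataset$truth, file.path(out_dir, "truth.tsv"), na = "",
                   progress = FALSE)
  rlang::inform(sprintf("simulated %d proteins, %d sites (seed %d)",
                        nrow(dataset$proteins), nrow(dataset$sites), config$seed))
  write_manifest(out_dir, "simulate", config)
  invisible(dataset)
}

#' @describeIn pipeline Estimate stoichiometry bounds. Keys: `out_dir`,
#'   `site_table`, `heavy_intensity_table` (required); `protein_table`,
#'   `c_max` (default 1), `bottom_fraction` (default 0.1), `thresholds`
#'   (default 0.02/0.05/0.1/1), `natural_only` (default TRUE), `col_map`,
#'   `ratio_orientation`. Writes `estimates.tsv`, `fractions.tsv` and the
#'   manifest; returns a list with `estimates`, `fractions`, `limit`.
#' @export
run_stoichiometry <- function(config = list()) {
  config <- load_config(config)
  config <- merge_config(
    list(c_max = 1.0, bottom_fraction = 0.10,
         thresholds = c(0.02, 0.05, 0.1, 1), natural_only = TRUE,
         ratio_orientation = "light_over_heavy", seed = 1L),
    config
  )
  for (key in c("site_table", "heavy_intensity_table")) {
    if (is.null(config[[key]])) {
      rlang::abort(sprintf("config key '%s' is required", key),
                   class = "acstoich_config_error")
    }
  }
  out_dir <- prepare_out_dir(config)
  sites <- read_site_table(config$site_table,
                           col_map = unlist(config$col_map),
                           ratio_orientation = config$ratio_orientation)
  proteins <- if (!is.null(config$protein_table)) {
    read_protein_table(config$protein_table, col_map = unlist(config$col_map),
                       ratio_orientation = config$ratio_orientation)
  } else NULL
  heavy <- readr::read_tsv(config$heavy_intensity_table,
                           col_types = readr::cols(.default = readr::col_double()),
                           progress = FALSE)[[1]]
  limit <- detection_limit(heavy, bottom_fraction = config$bottom_fraction)
  estimates <- estimate_stoichiometry(sites, proteins, limit,
                                      c_max = config$c_max,
                                      natural_only = config$natural_only)
  fractions <- stoichiometry_fractions(estimates, thresholds = config$thresholds)
  write_estimates(estimates, file.path(out_dir, "estimates.tsv"))
  readr::write_tsv(fractions, file.path(out_dir, "fractions.tsv"), progress = FALSE)
  counts <- table(estimates$sensitivity_class)
  rlang::inform(sprintf(
    "estimated %d sites (detection limit %.4g): %s", nrow(estimates), limit$value,
    paste(sprintf("%s=%d", names(counts), as.integer(counts)), collapse = ", ")))
  write_manifest(out_dir, "stoichiometry", config,
                 inputs = unlist(config[c("site_table", "protein_table",
                                          "heavy_intensity_table")]))
  invisible(list(estimates = estimates, fractions = fractions, limit = limit))
}

#' @describeIn pipeline Protein-corrected compartment dynamics. Keys:
#'   `out_dir`, `site_table`, `protein_table` (required);
#'   `annotation_table` (optional; enrichment is skipped with a notice when
#'   absent), `reference` (default `"cytoplasm"`), `selection_fold`
#'   (corrected-ratio threshold defining the enrichment selection, default
#'   2), `col_map`, `ratio_orientation`. Writes `compartment_summaries.tsv`
#'   (and `enrichment.tsv` when applicable) plus the manifest; returns a
#'   list with `corrected`, `summaries`, `enrichment`.
#' @export
run_dynamics <- function(config = list()) {
  config <- load_config(config)
  config <- merge_config(
    list(reference = "cytoplasm", selection_fold = 2,
         ratio_orientation = "light_over_heavy", seed = 1L),
    config
  )
  for (key in c("site_table", "protein_table")) {
    if (is.null(config[[key]])) {
      rlang::abort(sprintf("config key '%s' is required", key),
                   class = "acstoich_config_error")
    }
  }
  out_dir <- prepare_out_dir(config)
  sites <- read_site_table(config$site_table, col_map = unlist(config$col_map),
                           ratio_orientation = config$ratio_orientation)
  proteins <- read_protein_table(config$protein_table,
                                 col_map = unlist(config$col_map),
                                 ratio_orientation = config$ratio_orientation)
  if (all(!nzchar(proteins$localizations))) {
    rlang::warn("protein table carries no localizations; compartment summaries will be empty")
  }
  corrected <- corrected_site_ratios(sites, proteins)
  loc <- dplyr::select(proteins, "protein_id", "localizations")
  corrected <- dplyr::left_join(corrected, loc, by = "protein_id")
  corrected$compartment <- exclusive_localization(corrected$localizations)
  summaries <- compartment_summaries(
    dplyr::transmute(corrected, compartment = .data$compartment,
                     ratio = .data$corrected_ratio),
    reference = config$reference
  )
  readr::write_tsv(tidy(summaries), file.path(out_dir, "compartment_summaries.tsv"),
                   na = "", progress = FALSE)
  enrichment <- NULL
  if (!is.null(config$annotation_table)) {
    annotation <- read_annotation_table(config$annotation_table)
    hot <- corrected$protein_id[!is.na(corrected$corrected_ratio) &
                                  corrected$corrected_ratio > config$selection_fold]
    enrichment <- term_enrichment(unique(hot), unique(corrected$protein_id),
                                  annotation)
    readr::write_tsv(enrichment, file.path(out_dir, "enrichment.tsv"),
                     progress = FALSE)
  } else {
    rlang::inform("no annotation table configured; enrichment skipped")
  }
  write_manifest(out_dir, "dynamics", config,
                 inputs = unlist(config[c("site_table", "protein_table",
                                          "annotation_table")]))
  invisible(list(corrected = corrected, summaries = summaries,
                 enrichment = enrichment))
}

#' @describeIn pipeline AQUA absolute stoichiometry report. Keys: `out_dir`,
#'   `aqua_table` (required), `ratio_table` (required; TSV with `peptide`
#'   and `ratio` columns giving each peptide's SILAC fold increase).
#'   Peptides missing from the ratio table are listed and skipped. Writes
#'   `aqua_report.tsv` plus the manifest; returns the report invisibly.
#' @export
run_aqua <- function(config = list()) {
  config <- load_config(config)
  config <- merge_config(list(seed = 1L), config)
  for (key in c("aqua_table", "ratio_table")) {
    if (is.null(config[[key]])) {
      rlang::abort(sprintf("config key '%s' is required", key),
                   class = "acstoich_config_error")
    }
  }
  out_dir <- prepare_out_dir(config)
  aqua <- read_aqua_table(config$aqua_table, col_map = unlist(config$col_map))
  ratios <- readr::read_tsv(config$ratio_table,
                            col_types = readr::cols(peptide = readr::col_character(),
                                                    ratio = readr::col_double(),
                                                    .default = readr::col_guess()),
                            progress = FALSE)
  measured <- aqua_stoichiometry(aqua)
  joined <- dplyr::left_join(measured, dplyr::select(ratios, "peptide", "ratio"),
                             by = "peptide")
  unmatched <- joined$peptide[is.na(joined$ratio)]
  if (length(unmatched) > 0) {
    rlang::warn(c("peptide(s) without a SILAC ratio were skipped:",
                  stats::setNames(unmatched, rep("*", length(unmatched)))))
    joined <- dplyr::filter(joined, !is.na(.data$ratio))
  }
  report <- aqua_report(joined)
  readr::write_tsv(report, file.path(out_dir, "aqua_report.tsv"), na = "",
                   progress = FALSE)
  write_manifest(out_dir, "aqua", config,
                 inputs = unlist(config[c("aqua_table", "ratio_table")]))
  invisible(report)
}
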