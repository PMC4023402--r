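#' Readers for SILAC quantification tables
#'
#' Tab-separated tables modeled on search-engine output are the entry point of
#' the pipeline: an acetyl-site table (one row per site with light/heavy
#' intensities and a SILAC ratio), a protein table (intensity, ratio, iBAQ
#' inputs, subcellular localization), an AQUA table (acetylated/unmodified
#' peptide intensities plus heavy-standard spike amounts) and a TMT reporter
#' table. Because published supplementary schemas vary, every reader accepts a
#' `col_map` renaming file columns onto the canonical names, and the site
#' reader accepts a `ratio_orientation` flag so tables storing heavy/light are
#' converted to the light(treated)/heavy(untreated) orientation used
#' throughout.
#'
#' Rows violating the table's invariants are dropped, each with exactly one
#' row-indexed diagnostic; diagnostics are attached to the result as the
#' `"problems"` attribute and summarized in a warning. A missing required
#' column raises a format error naming the column.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(protein_id = "Protein", silac_ratio = "Ratio H/L")`.
#' @param ratio_orientation `"light_over_heavy"` (default) if the file's ratio
#'   column is already L/H (treated/untreated), `"heavy_over_light"` to invert
#'   at read time.
#' @return A tibble, one row per valid input row, with the canonical columns
#'   of the table type; see Details of each reader.
#' @name readers
NULL

# internal: read a TSV as character columns, apply col_map, require columns
read_raw_table <- function(path, col_map, required) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path), class = "acstoich_io_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = c("", "NA"))
  raw <- tibble::as_tibble(raw)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      file_col <- col_map[[canon]]
      if (file_col %in% names(raw)) {
        names(raw)[names(raw) == file_col] <- canon
      }
    }
  }
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort_format(sprintf("missing required column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  raw
}

# internal: convert a character column to numeric, recording per-row problems.
# Returns list(values, bad_rows, messages).
coerce_numeric <- function(x, column) {
  suppress <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(suppress))
  list(values = suppress, bad_rows = bad,
       messages = sprintf("row %d: non-numeric value %s in column '%s'",
                          bad, sQuote(x[bad]), column))
}

# internal: finalize a validated table — drop bad rows, attach diagnostics
finalize_table <- function(tbl, bad_rows, messages) {
  if (length(bad_rows) > 0) {
    ord <- order(bad_rows)
    problems <- tibble::tibble(row = bad_rows[ord], message = messages[ord])
    tbl <- tbl[-unique(bad_rows), , drop = FALSE]
    rlang::warn(sprintf("dropped %d invalid row(s); see attr(x, \"problems\")",
                        length(unique(bad_rows))))
    attr(tbl, "problems") <- problems
  } else {
    attr(tbl, "problems") <- tibble::tibble(row = integer(), message = character())
  }
  tbl
}

#' @describeIn readers Acetylation-site table. Required columns:
#'   `protein_id`, `position`, `peptide`, `light_intensity`; optional:
#'   `heavy_intensity`, `silac_ratio`, `naturally_occurring`. The SILAC ratio
#'   is computed as light/heavy when absent and both channels were observed;
#'   sites with no heavy signal keep an `NA` ratio (their minimum ratio is
#'   estimated later against the detection limit). Peptides must carry at
#'   least one `"(ac)"` marker and positions are 1-based residue indices.
#' @export
read_site_table <- function(path, col_map = NULL,
                            ratio_orientation = c("light_over_heavy", "heavy_over_light")) {
  ratio_orientation <- match.arg(ratio_orientation)
  raw <- read_raw_table(path, col_map,
                        required = c("protein_id", "position", "peptide", "light_intensity"))
  n <- nrow(raw)
  bad_rows <- integer(); messages <- character()
  note <- function(rows, msgs) {
    bad_rows <<- c(bad_rows, rows); messages <<- c(messages, msgs)
  }

  pos <- coerce_numeric(raw$position, "position")
  light <- coerce_numeric(raw$light_intensity, "light_intensity")
  note(pos$bad_rows, pos$messages); note(light$bad_rows, light$messages)

  heavy <- if ("heavy_intensity" %in% names(raw)) {
    h <- coerce_numeric(raw$heavy_intensity, "heavy_intensity")
    note(h$bad_rows, h$messages); h$values
  } else rep(NA_real_, n)
  ratio <- if ("silac_ratio" %in% names(raw)) {
    r <- coerce_numeric(raw$silac_ratio, "silac_ratio")
    note(r$bad_rows, r$messages); r$values
  } else rep(NA_real_, n)
  if (ratio_orientation == "heavy_over_light") ratio <- 1 / ratio

  natural <- if ("naturally_occurring" %in% names(raw)) {
    toupper(trimws(raw$naturally_occurring)) %in% c("TRUE", "T", "1", "YES")
  } else rep(TRUE, n)

  # compute L/H where the file gave both channels but no ratio
  computable <- is.na(ratio) & !is.na(light$values) & !is.na(heavy) &
    light$values > 0 & heavy > 0
  ratio[computable] <- light$values[computable] / heavy[computable]

  # row invariants
  chk <- function(cond, msg) {
    rows <- which(!is.na(cond) & cond)
    note(rows, sprintf("row %d: %s", rows, msg))
  }
  chk(pos$values < 1, "position must be >= 1")
  chk(light$values < 0, "light_intensity must be >= 0")
  chk(heavy < 0, "heavy_intensity must be >= 0")
  chk(!is.na(ratio) & ratio <= 0, "silac_ratio must be > 0")
  no_ac <- which(!grepl("(ac)", raw$peptide, fixed = TRUE))
  note(no_ac, sprintf("row %d: peptide lacks an '(ac)' marker", no_ac))
  # a file-supplied ratio is only meaningful when both channels were observed;
  # checkable only when the file reports the heavy channel at all
  orphan <- if (all(c("silac_ratio", "heavy_intensity") %in% names(raw))) {
    which(!is.na(ratio) & (is.na(heavy) | heavy == 0) & !computable)
  } else integer(0)
  note(orphan,
       sprintf("row %d: silac_ratio given but heavy channel not observed", orphan))

  out <- tibble::tibble(
    protein_id = raw$protein_id,
    position = as.integer(pos$values),
    peptide = raw$peptide,
    light_intensity = light$values,
    heavy_intensity = heavy,
    silac_ratio = ratio,
    naturally_occurring = natural
  )
  finalize_table(out, bad_rows, messages)
}

#' @describeIn readers Protein table. Required columns: `protein_id`,
#'   `total_intensity`; optional: `silac_ratio`, `sequence`,
#'   `n_observable_peptides`, `localizations` (semicolon-separated compartment
#'   labels). When `n_observable_peptides` is absent but a sequence is
#'   present, it is derived by [count_observable_peptides()]; an `ibaq` column
#'   is added wherever both inputs exist.
#' @export
read_protein_table <- function(path, col_map = NULL,
                               ratio_orientation = c("light_over_heavy", "heavy_over_light")) {
  ratio_orientation <- match.arg(ratio_orientation)
  raw <- read_raw_table(path, col_map, required = c("protein_id", "total_intensity"))
  n <- nrow(raw)
  bad_rows <- integer(); messages <- character()
  note <- function(rows, msgs) {
    bad_rows <<- c(bad_rows, rows); messages <<- c(messages, msgs)
  }

  intensity <- coerce_numeric(raw$total_intensity, "total_intensity")
  note(intensity$bad_rows, intensity$messages)
  ratio <- if ("silac_ratio" %in% names(raw)) {
    r <- coerce_numeric(raw$silac_ratio, "silac_ratio")
    note(r$bad_rows, r$messages); r$values
  } else rep(NA_real_, n)
  if (ratio_orientation == "heavy_over_light") ratio <- 1 / ratio
  n_obs <- if ("n_observable_peptides" %in% names(raw)) {
    v <- coerce_numeric(raw$n_observable_peptides, "n_observable_peptides")
    note(v$bad_rows, v$messages); v$values
  } else rep(NA_real_, n)
  sequence <- if ("sequence" %in% names(raw)) raw$sequence else rep(NA_character_, n)
  locs <- if ("localizations" %in% names(raw)) raw$localizations else rep(NA_character_, n)

  # derive the observable-peptide count from the sequence when not given
  derive <- is.na(n_obs) & !is.na(sequence) & nzchar(sequence)
  n_obs[derive] <- vapply(sequence[derive], count_observable_peptides, numeric(1))

  chk <- function(cond, msg) {
    rows <- which(!is.na(cond) & cond)
    note(rows, sprintf("row %d: %s", rows, msg))
  }
  chk(intensity$values < 0, "total_intensity must be >= 0")
  chk(!is.na(ratio) & ratio <= 0, "silac_ratio must be > 0")
  chk(!is.na(n_obs) & n_obs < 1, "n_observable_peptides must be >= 1")

  ibaq <- ifelse(!is.na(n_obs) & n_obs >= 1, intensity$values / n_obs, NA_real_)

  out <- tibble::tibble(
    protein_id = raw$protein_id,
    total_intensity = intensity$values,
    silac_ratio = ratio,
    sequence = sequence,
    n_observable_peptides = ifelse(is.na(n_obs), NA_integer_, as.integer(n_obs)),
    ibaq = ibaq,
    localizations = ifelse(is.na(locs), "", locs)
  )
  finalize_table(out, bad_rows, messages)
}

#' @describeIn readers AQUA table. Required columns: `peptide`,
#'   `ac_light_intensity`, `ac_standard_intensity`, `unmod_light_intensity`,
#'   `unmod_standard_intensity`, `ac_spike_amount`, `unmod_spike_amount`; all
#'   must be strictly positive.
#' @export
read_aqua_table <- function(path, col_map = NULL) {
  num_cols <- c("ac_light_intensity", "ac_standard_intensity",
                "unmod_light_intensity", "unmod_standard_intensity",
                "ac_spike_amount", "unmod_spike_amount")
  raw <- read_raw_table(path, col_map, required = c("peptide", num_cols))
  bad_rows <- integer(); messages <- character()
  vals <- list()
  for (col in num_cols) {
    v <- coerce_numeric(raw[[col]], col)
    bad_rows <- c(bad_rows, v$bad_rows); messages <- c(messages, v$messages)
    bad <- which(!is.na(v$values) & v$values <= 0)
    bad_rows <- c(bad_rows, bad)
    messages <- c(messages, sprintf("row %d: '%s' must be > 0", bad, col))
    vals[[col]] <- v$values
  }
  out <- tibble::as_tibble(c(list(peptide = raw$peptide), vals))
  finalize_table(out, bad_rows, messages)
}

#' @describeIn readers TMT reporter table. Required columns: `peptide`,
#'   `is_acetylated`, `parent_purity`; every column whose name starts with
#'   `reporter` is treated as one reporter channel. Reporter intensities must
#'   be non-negative and parent-ion purity in \[0, 1\].
#' @export
read_tmt_table <- function(path, col_map = NULL) {
  raw <- read_raw_table(path, col_map,
                        required = c("peptide", "is_acetylated", "parent_purity"))
  reporter_cols <- grep("^reporter", names(raw), value = TRUE)
  if (length(reporter_cols) == 0) {
    abort_format("no reporter intensity columns found (names must start with 'reporter')")
  }
  bad_rows <- integer(); messages <- character()
  purity <- coerce_numeric(raw$parent_purity, "parent_purity")
  bad_rows <- c(bad_rows, purity$bad_rows); messages <- c(messages, purity$messages)
  bad <- which(!is.na(purity$values) & (purity$values < 0 | purity$values > 1))
  bad_rows <- c(bad_rows, bad)
  messages <- c(messages, sprintf("row %d: parent_purity must be in [0, 1]", bad))
  vals <- list()
  for (col in reporter_cols) {
    v <- coerce_numeric(raw[[col]], col)
    bad_rows <- c(bad_rows, v$bad_rows); messages <- c(messages, v$messages)
    neg <- which(!is.na(v$values) & v$values < 0)
    bad_rows <- c(bad_rows, neg)
    messages <- c(messages, sprintf("row %d: '%s' must be >= 0", neg, col))
    vals[[col]] <- v$values
  }
  out <- tibble::as_tibble(c(
    list(peptide = raw$peptide,
         is_acetylated = toupper(trimws(raw$is_acetylated)) %in% c("TRUE", "T", "1", "YES"),
         parent_purity = purity$values),
    vals
  ))
  finalize_table(out, bad_rows, messages)
}

#' Read an annotation map (protein to term sets)
#'
#' A two-column tab-separated file: `protein_id` and `terms`
#' (semicolon-separated term identifiers). Returned in long form, one row per
#' protein/term pair, ready for [term_enrichment()]. Proteins listed with an
#' empty term set are rejected with a row diagnostic.
#'
#' @inheritParams readers
#' @return Tibble with columns `protein_id`, `term`.
#' @export
read_annotation_table <- function(path, col_map = NULL) {
  raw <- read_raw_table(path, col_map, required = c("protein_id", "terms"))
  empty <- which(is.na(raw$terms) | !nzchar(trimws(raw$terms)))
  out <- finalize_table(raw, empty,
                        sprintf("row %d: empty term set", empty))
  problems <- attr(out, "problems")
  out <- tidyr::separate_longer_delim(out, "terms", delim = ";")
  out <- dplyr::transmute(out,
                          protein_id = .data$protein_id,
                          term = trimws(.data$terms))
  out <- dplyr::filter(out, nzchar(.data$term))
  attr(out, "problems") <- problems
  out
}

#' Read protein sequences from a FASTA file
#'
#' Identifiers are the first whitespace-delimited token of each header line.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector mapping protein id to amino-acid sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path), class = "acstoich_io_error")
  }
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- tryCatch(Biostrings::readAAStringSet(path),
                    error = function(e) abort_format(sprintf(
                      "could not parse FASTA file '%s': %s", path, conditionMessage(e))))
    seqs <- as.character(set)
    ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  } else {
    lines <- readLines(path, warn = FALSE)
    headers <- grep("^>", lines)
    if (length(headers) == 0) abort_format(sprintf("no FASTA records in '%s'", path))
    ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[headers])
    bounds <- c(headers, length(lines) + 1L)
    seqs <- vapply(seq_along(headers), function(i) {
      paste(lines[seq(bounds[i] + 1L, bounds[i + 1L] - 1L)], collapse = "")
    }, character(1))
  }
  if (length(seqs) == 0) abort_format(sprintf("no FASTA records in '%s'", path))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort_format(sprintf("duplicate FASTA identifier(s): %s", paste(dup, collapse = ", ")))
  }
  stats::setNames(gsub("\\s", "", seqs), ids)
}
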