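#' Round half away from zero at a fixed number of decimals
#'
#' Report columns mirror the print precision of published stoichiometry
#' tables, which round half-up (0.0755 prints as 0.08). R's `round()` uses
#' banker's rounding, so reporting layers use this helper instead. Internal
#' computations always stay at full precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(0.0755, 2) # 0.08
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# internal: stop with a classed error, tidyverse-style
abort_domain <- function(msg, class = "acstoich_domain_error") {
  rlang::abort(msg, class = class)
}

abort_format <- function(msg) {
  rlang::abort(msg, class = "acstoich_format_error")
}

# internal: check a scalar is a positive finite number
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort_domain(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}

# internal: parse a semicolon-separated localization field into a character
# vector of compartment labels (empty string -> character(0))
parse_localizations <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  labs <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  labs[nzchar(labs)]
}
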