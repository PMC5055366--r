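#' Round half away from zero
#'
#' Commercial ("half-up") rounding, the convention used throughout the
#' spawning-fraction arithmetic: 0.405 rounds to 0.41, 0.205 to 0.21.
#' Base R's `round()` rounds half to even and would give 0.40 and 0.20,
#' which does not reproduce published spawning-interval tables.
#'
#' A guard of 1e-8 is added before truncation so that values that are
#' exactly representable halves in decimal but sit just below the half in
#' binary floating point (e.g. `1.62 / 4`) still round up.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return `x` rounded half away from zero to `digits` places.
#' @examples
#' round_half_up(0.405, 2) # 0.41, where round() gives 0.40
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-8) / p
}

# stop unless all ok, with a domain-error class
check_positive <- function(x, name, strict = TRUE) {
  bad <- if (strict) any(x <= 0, na.rm = TRUE) else any(x < 0, na.rm = TRUE)
  if (bad || anyNA(x)) {
    abort(
      sprintf("`%s` must be %s and non-missing.", name,
              if (strict) "> 0" else ">= 0"),
      class = "fecundr_domain_error"
    )
  }
  invisible(x)
}

# timestamped progress notes; results never go through this channel
fecundr_log <- function(..., level = "INFO") {
  inform(sprintf("[%s] %s %s", level,
                 format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 sprintf(...)))
}
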