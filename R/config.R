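#' Pipeline configuration
#'
#' Collects every tunable numeric convention of the pipeline in one
#' validated object, so that a whole analysis is reproducible from a single
#' seed and a single configuration.
#'
#' @param bin_width Histogram bin width in micrometres.
#' @param measurement_floor Smallest whole-oocyte diameter (um) that the
#'   imaging workflow measures reliably; records below it are excluded from
#'   histograms (and reported separately). Default 100 um.
#' @param phase_boundaries Strictly increasing diameter boundaries (um)
#'   between primary/transitional, transitional/secondary and
#'   secondary/maturation whole-mount phases. Default `c(300, 500, 1500)`.
#' @param maturation_overlap Lower diameter (um) from which a
#'   translucent/transparent oocyte is already classified as maturation
#'   even though opaque cells of that size are still secondary growth.
#'   Default 1200.
#' @param gap_band Diameter interval (um, half-open) inspected for the
#'   size gap between primary and secondary oocytes. Default `c(300, 500)`.
#' @param include_transitional Should transitional-growth oocytes count
#'   toward the advanced cohort in the determinate estimator? Default TRUE
#'   (early-run transitional cells recruit fully and spawn in the current
#'   year).
#' @param sf_digits Decimal places for the spawning-fraction / -interval
#'   rounding convention. Default 2.
#' @param si_floor Smallest admissible spawning-interval draw (days) in the
#'   Monte-Carlo simulation; smaller draws are rejected and resampled.
#'   Default 0.5.
#' @param n_draws,n_replicates Monte-Carlo size: fish per replicate and
#'   bootstrap replicates. Defaults 1000 and 1000.
#' @param seed Non-negative integer seed from which all randomness in a run
#'   flows.
#' @return A `fecundr_config` object (validated named list).
#' @export
fecundr_config <- function(bin_width = 50,
                           measurement_floor = 100,
                           phase_boundaries = c(300, 500, 1500),
                           maturation_overlap = 1200,
                           gap_band = c(300, 500),
                           include_transitional = TRUE,
                           sf_digits = 2,
                           si_floor = 0.5,
                           n_draws = 1000,
                           n_replicates = 1000,
                           seed = 1) {
  cfg <- list(
    bin_width = bin_width, measurement_floor = measurement_floor,
    phase_boundaries = phase_boundaries,
    maturation_overlap = maturation_overlap, gap_band = gap_band,
    include_transitional = isTRUE(include_transitional),
    sf_digits = sf_digits, si_floor = si_floor,
    n_draws = n_draws, n_replicates = n_replicates, seed = seed
  )
  validate_config(cfg)
  structure(cfg, class = "fecundr_config")
}

validate_config <- function(cfg) {
  check_positive(cfg$bin_width, "bin_width")
  check_positive(cfg$measurement_floor, "measurement_floor", strict = FALSE)
  if (length(cfg$phase_boundaries) != 3 ||
      is.unsorted(cfg$phase_boundaries, strictly = TRUE)) {
    abort("`phase_boundaries` must be three strictly increasing values.",
          class = "fecundr_domain_error")
  }
  if (length(cfg$gap_band) != 2 || diff(cfg$gap_band) <= 0) {
    abort("`gap_band` must be an increasing interval.",
          class = "fecundr_domain_error")
  }
  if (cfg$seed < 0 || cfg$seed != round(cfg$seed)) {
    abort("`seed` must be a non-negative integer.",
          class = "fecundr_domain_error")
  }
  check_positive(cfg$n_draws, "n_draws")
  check_positive(cfg$n_replicates, "n_replicates")
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Fields missing from the file keep their [fecundr_config()] defaults;
#' unknown fields are rejected.
#'
#' @param path Path to a YAML file.
#' @return A `fecundr_config` object.
#' @export
read_fecundr_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path),
          class = "fecundr_io_error")
  }
  user <- yaml::read_yaml(path)
  known <- names(formals(fecundr_config))
  extra <- setdiff(names(user), known)
  if (length(extra)) {
    abort(sprintf("Unknown config fields: %s", toString(extra)),
          class = "fecundr_schema_error")
  }
  do.call(fecundr_config, user)
}

#' @export
print.fecundr_config <- function(x, ...) {
  cat("<fecundr_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, toString(x[[nm]])))
  invisible(x)
}
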