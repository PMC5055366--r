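#' @name table-schemas
#' @title Tabular interchange formats
#'
#' @description
#' The pipeline exchanges four plain CSV tables (comma-separated, UTF-8,
#' ISO-8601 dates, empty fields for missing values):
#'
#' * `fish`: `fish_id, date, site, fork_length_mm, total_mass_g,
#'   ovary_mass_g, age_yr, macro_class, maos, pof_age` — one sampled
#'   female per row. `macro_class` is the macroscopic maturity class
#'   A (developing), B (hydrated), C (running ripe), D (partially spent),
#'   E (spent), F (resting); `maos` is the most-advanced-oocyte-stage
#'   histology code (PE, C1, C2, V1, V2, NM1, NM2, NM3, H, O);
#'   `pof_age` is the postovulatory-follicle age class
#'   (none, POF0, POF1, POF2).
#' * `oocytes`: `fish_id, diameter_um, phase, histology_stage` — one
#'   measured whole-oocyte diameter per row.
#' * `subsamples`: `fish_id, subsample_mass_g, count_primary,
#'   count_transitional, count_secondary, count_maturation` — one weighed
#'   gravimetric subsample with phase-resolved cell counts.
#' * `markers`: `date, site, n_females, p_day_minus1, p_day0, p_day_plus1,
#'   p_day_plus2` — per sampling date, the proportions of females bearing
#'   each day-adjusted spawning marker. The classes are not mutually
#'   exclusive, so the proportions may sum to more than 1.
NULL

.macro_classes <- c("A", "B", "C", "D", "E", "F")
.maos_codes    <- c("PE", "C1", "C2", "V1", "V2", "NM1", "NM2", "NM3", "H", "O")
.pof_codes     <- c("none", "POF0", "POF1", "POF2")
.phases        <- c("primary", "transitional", "secondary", "maturation")

.fish_cols <- c("fish_id", "date", "site", "fork_length_mm", "total_mass_g",
                "ovary_mass_g", "age_yr", "macro_class", "maos", "pof_age")
.oocyte_cols <- c("fish_id", "diameter_um", "phase", "histology_stage")
.subsample_cols <- c("fish_id", "subsample_mass_g", "count_primary",
                     "count_transitional", "count_secondary",
                     "count_maturation")
.marker_cols <- c("date", "site", "n_females", "p_day_minus1", "p_day0",
                  "p_day_plus1", "p_day_plus2")

read_checked_csv <- function(path, required, col_types) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "fecundr_io_error")
  }
  hdr <- names(readr::read_csv(path, n_max = 0,
                               col_types = readr::cols(.default = "c"),
                               progress = FALSE))
  missing <- setdiff(required, hdr)
  if (length(missing)) {
    abort(sprintf("%s is missing mandatory column(s): %s",
                  basename(path), toString(missing)),
          class = "fecundr_schema_error")
  }
  x <- readr::read_csv(path, col_types = col_types, progress = FALSE)
  x[required]
}

row_errors <- function(ok, what) {
  if (all(ok)) return(invisible(NULL))
  rows <- which(!ok)
  abort(sprintf("%s in row(s): %s", what,
                toString(head(rows, 10))),
        class = "fecundr_validation_error")
}

check_enum <- function(x, allowed, col) {
  bad <- !is.na(x) & !(x %in% allowed)
  row_errors(!bad, sprintf("`%s` outside {%s}", col, toString(allowed)))
}

#' Read and validate a fish table
#'
#' Reads the `fish` CSV schema (see [table-schemas]) and enforces the row
#' invariants: positive fork length, `0 < ovary_mass < total_mass`, and
#' enumeration membership for `macro_class`, `maos` and `pof_age`.
#' Offending rows are named in the error. Row order is preserved; missing
#' ages (and other empty fields) propagate as `NA`.
#'
#' @param path Path to a CSV file.
#' @return A tibble, one validated row per female.
#' @export
read_fish_table <- function(path) {
  x <- read_checked_csv(path, .fish_cols, readr::cols(
    fish_id = "c", date = readr::col_date(), site = "c",
    fork_length_mm = "d", total_mass_g = "d", ovary_mass_g = "d",
    age_yr = "i", macro_class = "c", maos = "c", pof_age = "c"
  ))
  validate_fish(x)
}

validate_fish <- function(x) {
  row_errors(is.na(x$fork_length_mm) | x$fork_length_mm > 0,
             "`fork_length_mm` must be > 0")
  row_errors(is.na(x$ovary_mass_g) | x$ovary_mass_g > 0,
             "`ovary_mass_g` must be > 0")
  both <- !is.na(x$ovary_mass_g) & !is.na(x$total_mass_g)
  row_errors(!both | x$ovary_mass_g < x$total_mass_g,
             "`ovary_mass_g` must be smaller than `total_mass_g`")
  check_enum(x$macro_class, .macro_classes, "macro_class")
  check_enum(x$maos, .maos_codes, "maos")
  check_enum(x$pof_age, .pof_codes, "pof_age")
  x
}

#' Read whole-oocyte diameter measurements
#' @inheritParams read_fish_table
#' @return A tibble of oocyte records (`diameter_um` > 0 enforced).
#' @export
read_oocyte_table <- function(path) {
  x <- read_checked_csv(path, .oocyte_cols, readr::cols(
    fish_id = "c", diameter_um = "d", phase = "c", histology_stage = "c"
  ))
  row_errors(!is.na(x$diameter_um) & x$diameter_um > 0,
             "`diameter_um` must be > 0")
  check_enum(x$phase, .phases, "phase")
  x
}

#' Read gravimetric subsamples
#' @inheritParams read_fish_table
#' @return A tibble of subsample rows (positive mass, non-negative counts).
#' @export
read_subsample_table <- function(path) {
  x <- read_checked_csv(path, .subsample_cols, readr::cols(
    fish_id = "c", subsample_mass_g = "d", .default = "d"
  ))
  row_errors(!is.na(x$subsample_mass_g) & x$subsample_mass_g > 0,
             "`subsample_mass_g` must be > 0")
  for (cc in grep("^count_", names(x), value = TRUE)) {
    row_errors(!is.na(x[[cc]]) & x[[cc]] >= 0,
               sprintf("`%s` must be >= 0", cc))
  }
  x
}

#' Read a per-date spawning-marker table
#' @inheritParams read_fish_table
#' @return A tibble of marker rows; each proportion is checked to lie in
#'   `[0, 1]`. Proportions are not required to sum to 1 or less: a female
#'   can bear an oocyte-stage marker and a POF marker simultaneously.
#' @export
read_marker_table <- function(path) {
  x <- read_checked_csv(path, .marker_cols, readr::cols(
    date = readr::col_date(), site = "c", n_females = "i", .default = "d"
  ))
  row_errors(!is.na(x$n_females) & x$n_females > 0,
             "`n_females` must be > 0")
  for (cc in grep("^p_", names(x), value = TRUE)) {
    row_errors(!is.na(x[[cc]]) & x[[cc]] >= 0 & x[[cc]] <= 1,
               sprintf("`%s` must lie in [0, 1]", cc))
  }
  x
}

#' Write a pipeline table to CSV
#'
#' Writes with full numeric precision, ISO-8601 dates and empty fields for
#' missing values, so a write/read cycle reproduces every field exactly.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_fecundr_table <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(x)
}

#' Classify spawn status from postovulatory-follicle age
#'
#' Females without POFs are pre-spawning; any POF age class (POF0-POF2)
#' marks a female that has already spawned this season. A missing POF
#' record yields the explicit value `"unknown"` rather than a silent
#' default.
#'
#' @param pof_age Character vector with values in
#'   `c("none", "POF0", "POF1", "POF2")` or `NA`.
#' @return Character vector in `c("pre_spawning", "spawning", "unknown")`.
#' @examples
#' classify_spawn_status(c("none", "POF1", NA))
#' @export
classify_spawn_status <- function(pof_age) {
  check_enum(pof_age, .pof_codes, "pof_age")
  dplyr::case_when(
    is.na(pof_age) ~ "unknown",
    pof_age == "none" ~ "pre_spawning",
    TRUE ~ "spawning"
  )
}

#' Add a spawn-status column to a fish table
#'
#' @param fish A fish tibble (see [table-schemas]).
#' @return `fish` with a `spawn_status` column from
#'   [classify_spawn_status()].
#' @export
add_spawn_status <- function(fish) {
  dplyr::mutate(fish, spawn_status = classify_spawn_status(.data$pof_age))
}

fecundr_extdata <- function(file) {
  path <- system.file("extdata", file, package = "fecundr", mustWork = TRUE)
  path
}

#' Connecticut River 2015 profile females
#'
#' The twelve females selected for whole-oocyte diameter profiling in the
#' 2015 Connecticut River American shad spawning run: six upstream
#' (developing, Class A) and six downstream (spent Class E / resting
#' Class F) migrants, with fork length, age (one age unavailable),
#' gonadosomatic index, most advanced oocyte stage and POF presence.
#'
#' @return A tibble with columns `migration, location, maturity_class,
#'   date, fork_length_mm, age_yr, gsi, maos, pofs_present, panel`.
#' @export
shad_profile_females <- function() {
  readr::read_csv(fecundr_extdata("shad_2015_profile_females.csv"),
                  col_types = readr::cols(
                    date = readr::col_date(), fork_length_mm = "d",
                    age_yr = "i", gsi = "d", pofs_present = "l",
                    .default = "c"
                  ), progress = FALSE)
}

#' Connecticut River 2015 spawning-marker proportions
#'
#' Per sampling date (twelve dates, May-June 2015, Hadley Falls / Cabot /
#' Vernon), the proportions of histologically examined females bearing
#' each day-adjusted spawning marker, together with the published
#' spawning fraction (SF) and spawning interval (SI, days). The marker
#' classes are: day -1 (MAOS = NM1), day 0 (MAOS = NM2/NM3/H, or POF0),
#' day +1 (POF1, 12-24 h), day +2 (POF2, 24-48 h). Classes co-occur, so
#' a row's proportions can sum to more than 1.
#'
#' @return A tibble in the `markers` schema (see [table-schemas]) plus
#'   the published `sf` and `si` columns.
#' @export
shad_marker_proportions <- function() {
  readr::read_csv(fecundr_extdata("shad_2015_spawning_markers.csv"),
                  col_types = readr::cols(
                    date = readr::col_date(), site = "c", n_females = "i",
                    .default = "d"
                  ), progress = FALSE)
}
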