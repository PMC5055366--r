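#' Day-adjusted spawning-marker classes
#'
#' Each histological marker dates a female relative to a spawning event
#' (day 0 = the spawning day):
#'
#' * day -1 — MAOS = NM1 (early nucleus migration; spawns tomorrow)
#' * day  0 — MAOS = NM2, NM3 or H (spawns today), or POF0 (fresh
#'   postovulatory follicle: spawned today)
#' * day +1 — POF1 (12-24 h old POF)
#' * day +2 — POF2 (24-48 h old POF)
#'
#' A female can carry an oocyte-stage marker and a POF marker at the same
#' time (e.g. NM1 with POF2: spawned two days ago, spawns again
#' tomorrow), so the classes are not mutually exclusive and a fish can
#' contribute to two day classes at once.
#'
#' @param maos Most-advanced-oocyte-stage codes
#'   (PE, C1, C2, V1, V2, NM1, NM2, NM3, H, O) or `NA`.
#' @param pof_age POF age classes (none, POF0, POF1, POF2) or `NA`.
#' @return Tibble of logical contribution columns
#'   `day_minus1, day0, day_plus1, day_plus2`, one row per input fish.
#'   Fish bearing no marker (e.g. MAOS = V2, no POF) have all-FALSE rows.
#' @examples
#' marker_day_offset("NM1", "POF2") # contributes to day -1 and day +2
#' @export
marker_day_offset <- function(maos, pof_age) {
  n <- max(length(maos), length(pof_age))
  maos <- rep_len(maos, n)
  pof_age <- rep_len(pof_age, n)
  check_enum(maos, .maos_codes, "maos")
  check_enum(pof_age, .pof_codes, "pof_age")
  tibble(
    day_minus1 = !is.na(maos) & maos == "NM1",
    day0 = (!is.na(maos) & maos %in% c("NM2", "NM3", "H")) |
      (!is.na(pof_age) & pof_age == "POF0"),
    day_plus1 = !is.na(pof_age) & pof_age == "POF1",
    day_plus2 = !is.na(pof_age) & pof_age == "POF2"
  )
}

#' Aggregate fish records into per-date marker proportions
#'
#' Computes, for every date-site sample, the proportion of females bearing
#' each day-adjusted marker class (independently per class, since classes
#' co-occur), yielding the `markers` schema of [table-schemas].
#'
#' @param fish A fish tibble with `date`, `site`, `maos`, `pof_age`.
#' @return A marker tibble: `date, site, n_females, p_day_minus1, p_day0,
#'   p_day_plus1, p_day_plus2`.
#' @export
marker_proportions <- function(fish) {
  contrib <- marker_day_offset(fish$maos, fish$pof_age)
  dplyr::bind_cols(fish[c("date", "site")], contrib) |>
    dplyr::group_by(.data$date, .data$site) |>
    dplyr::summarise(
      n_females = dplyr::n(),
      p_day_minus1 = mean(.data$day_minus1),
      p_day0 = mean(.data$day0),
      p_day_plus1 = mean(.data$day_plus1),
      p_day_plus2 = mean(.data$day_plus2),
      .groups = "drop"
    )
}

#' Spawning fraction from day-adjusted marker proportions
#'
#' Each marker class yields its own estimate of the fraction of females
#' spawning per day; the final spawning fraction is their mean, rounded
#' half-up to `digits` decimals (the convention that reproduces published
#' spawning-interval tables).
#'
#' @param p_day_minus1,p_day0,p_day_plus1,p_day_plus2 Proportions in
#'   `[0, 1]` (vectorized).
#' @param digits Rounding digits, default 2.
#' @return Spawning fraction per day (rounded).
#' @examples
#' spawning_fraction(0.50, 0.34, 0.03, 0.75) # 0.41
#' @export
spawning_fraction <- function(p_day_minus1, p_day0, p_day_plus1,
                              p_day_plus2, digits = 2) {
  p <- cbind(p_day_minus1, p_day0, p_day_plus1, p_day_plus2)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("Marker proportions must lie in [0, 1].",
          class = "fecundr_domain_error")
  }
  round_half_up(rowMeans(p), digits)
}

#' Spawning interval
#'
#' The reciprocal of the (already rounded) spawning fraction, itself
#' rounded half-up to `digits` decimals. A zero spawning fraction (no
#' spawning activity in the sample) has no defined interval and returns
#' `NA` with a warning; such rows are excluded from pooling.
#'
#' @param sf Spawning fraction per day, in `[0, 1]`.
#' @param digits Rounding digits, default 2.
#' @return Spawning interval in days.
#' @examples
#' spawning_interval(0.32) # 3.13
#' @export
spawning_interval <- function(sf, digits = 2) {
  if (any(sf < 0 | sf > 1, na.rm = TRUE)) {
    abort("`sf` must lie in [0, 1].", class = "fecundr_domain_error")
  }
  if (any(sf == 0, na.rm = TRUE)) {
    warn("Spawning interval undefined where sf = 0; NA returned.")
  }
  ifelse(is.na(sf) | sf == 0, NA_real_, round_half_up(1 / sf, digits))
}

#' Build a spawning-fraction / spawning-interval table
#'
#' Applies [spawning_fraction()] and [spawning_interval()] to each row of
#' a marker table, mirroring the published per-date layout column for
#' column.
#'
#' @param markers A marker tibble (see [table-schemas] and
#'   [marker_proportions()]).
#' @param digits Rounding digits, default 2.
#' @return `markers` with `sf` and `si` columns appended (existing `sf` /
#'   `si` columns are recomputed).
#' @export
si_table <- function(markers, digits = 2) {
  markers |>
    dplyr::mutate(
      sf = spawning_fraction(.data$p_day_minus1, .data$p_day0,
                             .data$p_day_plus1, .data$p_day_plus2,
                             digits = digits),
      si = spawning_interval(sf, digits = digits)
    )
}

#' Pooled spawning-interval summary
#'
#' Unweighted mean, sample (n-1) standard deviation and range of the
#' per-date spawning intervals. Rows with undefined SI are dropped; with
#' fewer than two usable rows the standard deviation is undefined (`NA`).
#'
#' Pre-spawning samples (e.g. lower-river collections taken before
#' spawning begins) should be excluded upstream: their scarcity of POF
#' markers yields unrealistically long apparent intervals.
#'
#' @param rows A tibble with an `si` column (e.g. from [si_table()]).
#' @return One-row tibble: `n, mean_si, sd_si, min_si, max_si`.
#' @export
pooled_si_summary <- function(rows) {
  si <- rows$si[!is.na(rows$si)]
  tibble(
    n = length(si),
    mean_si = if (length(si)) mean(si) else NA_real_,
    sd_si = if (length(si) >= 2) sd(si) else NA_real_,
    min_si = if (length(si)) min(si) else NA_real_,
    max_si = if (length(si)) max(si) else NA_real_
  )
}
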