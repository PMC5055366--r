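#' Classify a whole oocyte into a developmental phase
#'
#' Maps measured whole-mount diameters (and, when recorded, appearance
#' under transmitted light or a histology stage) to the four whole-oocyte
#' phases:
#'
#' * primary growth — small (< 300 um), transparent (stages PE, C1)
#' * transitional growth — medium (300-500 um), translucent grey
#'   (C1, C2, V1)
#' * secondary growth — large (500-1500 um), opaque black (V1, V2, NM1)
#' * oocyte maturation — largest (1200-2000 um), translucent-transparent
#'   (NM2, NM3, H, O)
#'
#' Published size bands are approximate and overlap at 1200-1500 um, where
#' both late secondary-growth and maturing oocytes occur. Classification
#' is made total and deterministic by half-open intervals
#' `[0,300) [300,500) [500,1500) [1500,Inf)` on diameter, with two
#' overrides: in the 1200-1500 um overlap a translucent or transparent
#' cell is maturation (opaque stays secondary), and an unambiguous
#' histology stage, when supplied, takes precedence over size
#' (PE -> primary; C2 -> transitional; V2, NM1 -> secondary;
#' NM2, NM3, H, O -> maturation; C1 and V1 each span two phases and do
#' not override).
#'
#' @param diameter_um Positive numeric vector of diameters (um).
#' @param appearance Optional character vector in
#'   `c("transparent", "translucent", "opaque")` (or `NA`).
#' @param histology_stage Optional character vector of stage codes.
#' @param boundaries Phase size boundaries (um), default `c(300, 500, 1500)`.
#' @param maturation_overlap Diameter (um) above which non-opaque cells are
#'   already maturation, default 1200.
#' @return Character vector in
#'   `c("primary", "transitional", "secondary", "maturation")`.
#' @examples
#' classify_phase(c(250, 400, 800, 1600))
#' classify_phase(1300, appearance = "translucent") # maturation
#' classify_phase(1300, appearance = "opaque")      # secondary
#' @export
classify_phase <- function(diameter_um, appearance = NULL,
                           histology_stage = NULL,
                           boundaries = c(300, 500, 1500),
                           maturation_overlap = 1200) {
  check_positive(diameter_um, "diameter_um")
  n <- length(diameter_um)
  appearance <- appearance %||% rep(NA_character_, n)
  histology_stage <- histology_stage %||% rep(NA_character_, n)
  ok <- is.na(appearance) |
    appearance %in% c("transparent", "translucent", "opaque")
  row_errors(ok, "`appearance` must be transparent/translucent/opaque")
  check_enum(histology_stage, .maos_codes, "histology_stage")

  phase <- cut(diameter_um, breaks = c(0, boundaries, Inf), right = FALSE,
               labels = .phases)
  phase <- as.character(phase)

  # 1200-1500 um overlap: appearance decides; opaque stays secondary
  overlap <- diameter_um >= maturation_overlap & diameter_um < boundaries[3] &
    !is.na(appearance) & appearance %in% c("translucent", "transparent")
  phase[overlap] <- "maturation"

  # a decisive histology stage overrides pure size
  override <- c(PE = "primary", C2 = "transitional", V2 = "secondary",
                NM1 = "secondary", NM2 = "maturation", NM3 = "maturation",
                H = "maturation", O = "maturation")
  hit <- !is.na(histology_stage) & histology_stage %in% names(override)
  phase[hit] <- override[histology_stage[hit]]
  phase
}

#' Build a phase-resolved oocyte size-frequency histogram
#'
#' Bins whole-oocyte diameters into fixed-width classes, overlaid (not
#' stacked) per phase. Records below the measurement floor are excluded
#' from the bins and reported separately via `attr(, "n_excluded")`:
#' small previtellogenic cells are poorly captured by the imaging
#' workflow, so counts below the floor are not comparable.
#'
#' Records without a recorded `phase` are classified from diameter with
#' [classify_phase()].
#'
#' @param oocytes Tibble with at least `diameter_um`, optionally `phase`
#'   and `histology_stage` (the `oocytes` schema of [table-schemas]).
#' @param bin_width Bin width (um), default 50.
#' @param measurement_floor Exclusion floor (um), default 100.
#' @return A `phase_histogram` tibble with columns
#'   `bin_start, bin_end, phase, count` over the complete bin x phase
#'   grid, and attributes `n_input`, `n_excluded`, `bin_width`,
#'   `measurement_floor`.
#' @export
build_histogram <- function(oocytes, bin_width = 50,
                            measurement_floor = 100) {
  check_positive(bin_width, "bin_width")
  check_positive(measurement_floor, "measurement_floor", strict = FALSE)
  n_input <- nrow(oocytes)

  empty <- tibble(bin_start = numeric(), bin_end = numeric(),
                  phase = character(), count = integer())
  if (n_input == 0) {
    return(new_phase_histogram(empty, n_input = 0L, n_excluded = 0L,
                               bin_width = bin_width,
                               measurement_floor = measurement_floor))
  }
  check_positive(oocytes$diameter_um, "diameter_um")
  if (!"phase" %in% names(oocytes)) oocytes$phase <- NA_character_
  stage <- if ("histology_stage" %in% names(oocytes)) {
    oocytes$histology_stage
  }
  miss <- is.na(oocytes$phase)
  if (any(miss)) {
    oocytes$phase[miss] <- classify_phase(oocytes$diameter_um[miss],
                                          histology_stage = stage[miss])
  }
  check_enum(oocytes$phase, .phases, "phase")

  keep <- oocytes$diameter_um >= measurement_floor
  n_excluded <- sum(!keep)
  kept <- oocytes[keep, ]
  if (nrow(kept) == 0) {
    return(new_phase_histogram(empty, n_input = n_input,
                               n_excluded = n_excluded,
                               bin_width = bin_width,
                               measurement_floor = measurement_floor))
  }

  lo <- floor(measurement_floor / bin_width) * bin_width
  hi <- ceiling((max(kept$diameter_um) + 1e-9) / bin_width) * bin_width
  edges <- seq(lo, hi, by = bin_width)
  kept$bin_start <- edges[findInterval(kept$diameter_um, edges,
                                       rightmost.closed = FALSE)]
  grid <- tidyr::expand_grid(bin_start = edges[-length(edges)],
                             phase = .phases)
  counts <- dplyr::count(kept, .data$bin_start, .data$phase, name = "count")
  out <- dplyr::left_join(grid, counts, by = c("bin_start", "phase")) |>
    dplyr::mutate(count = as.integer(tidyr::replace_na(.data$count, 0L)),
                  bin_end = .data$bin_start + bin_width, .after = "bin_start")
  new_phase_histogram(out, n_input = n_input, n_excluded = n_excluded,
                      bin_width = bin_width,
                      measurement_floor = measurement_floor)
}

new_phase_histogram <- function(x, ...) {
  attrs <- list(...)
  for (nm in names(attrs)) attr(x, nm) <- attrs[[nm]]
  class(x) <- c("phase_histogram", class(x))
  x
}

#' Gap uncertainty
#'
#' Percentage of transitional-growth oocytes among transitional and
#' secondary oocytes combined. It quantifies how ambiguous the size gap
#' between the previtellogenic reservoir and the advanced (yolked) cohort
#' is, and hence the potential relative bias of a determinate fecundity
#' estimate that excludes transitional cells. 0% is an unambiguous,
#' complete gap.
#'
#' @param count_transitional,count_secondary Non-negative counts
#'   (vectorized).
#' @return `100 * T / (T + S)`, in percent; `NA` with a warning where both
#'   counts are zero (undefined).
#' @examples
#' gap_uncertainty(8, 92) # 8
#' @export
gap_uncertainty <- function(count_transitional, count_secondary) {
  check_positive(count_transitional, "count_transitional", strict = FALSE)
  check_positive(count_secondary, "count_secondary", strict = FALSE)
  tot <- count_transitional + count_secondary
  if (any(tot == 0)) {
    warn("gap_uncertainty undefined where both counts are zero; NA returned.")
  }
  ifelse(tot == 0, NA_real_, 100 * count_transitional / tot)
}

#' Detect the oocyte size gap
#'
#' Inspects a [build_histogram()] result inside a diameter band (default
#' the transitional range, 300-500 um). The gap is *complete* when no
#' transitional-phase cells fall in the band — the signature of
#' group-synchronous vitellogenesis once recruitment of the advanced
#' cohort is over. The whole-fish gap uncertainty accompanies the verdict.
#'
#' @param hist A `phase_histogram`.
#' @param band Length-2 numeric, half-open diameter interval (um).
#' @return One-row tibble:
#'   `complete_gap` (logical), `band_count` (all-phase count in the band),
#'   `band_transitional` (transitional count in the band) and
#'   `gap_uncertainty` (percent, from whole-fish phase totals).
#' @export
detect_size_gap <- function(hist, band = c(300, 500)) {
  stopifnot(inherits(hist, "phase_histogram"))
  if (nrow(hist) == 0) {
    abort("Cannot assess a size gap on an empty histogram.",
          class = "fecundr_range_error")
  }
  rng <- range(hist$bin_start, hist$bin_end)
  if (band[1] < rng[1] || band[2] > rng[2]) {
    abort(sprintf("band [%g, %g) lies outside the histogram range [%g, %g).",
                  band[1], band[2], rng[1], rng[2]),
          class = "fecundr_range_error")
  }
  in_band <- hist$bin_start < band[2] & hist$bin_end > band[1]
  trans_in_band <- sum(hist$count[in_band & hist$phase == "transitional"])
  totals <- tapply(hist$count, hist$phase, sum)
  gu <- gap_uncertainty(totals[["transitional"]], totals[["secondary"]])
  tibble(
    complete_gap = trans_in_band == 0L,
    band_count = sum(hist$count[in_band]),
    band_transitional = trans_in_band,
    gap_uncertainty = gu
  )
}

#' Plot a phase-resolved oocyte size-frequency histogram
#'
#' Overlaid (not stacked) translucent bars per phase, one panel per
#' histogram — the standard way an oocyte size-frequency distribution is
#' inspected for a size gap.
#'
#' @param object A `phase_histogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_histogram <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$bin_start + attr(object, "bin_width") / 2,
                 y = .data$count, fill = .data$phase)
  ) +
    ggplot2::geom_col(position = "identity", alpha = 0.55,
                      width = attr(object, "bin_width")) +
    ggplot2::labs(x = "Oocyte diameter (µm)", y = "Count",
                  fill = "Phase") +
    ggplot2::theme_minimal()
}

#' @export
print.phase_histogram <- function(x, ...) {
  cat(sprintf(
    "<phase_histogram> %d bins x 4 phases; %d measured, %d below %g um floor\n",
    length(unique(x$bin_start)), attr(x, "n_input") - attr(x, "n_excluded"),
    attr(x, "n_excluded"), attr(x, "measurement_floor")))
  print(as_tibble(unclass_attrs(x)), ...)
  invisible(x)
}

unclass_attrs <- function(x) {
  attr(x, "n_input") <- NULL
  attr(x, "n_excluded") <- NULL
  attr(x, "bin_width") <- NULL
  attr(x, "measurement_floor") <- NULL
  class(x) <- setdiff(class(x), "phase_histogram")
  x
}
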