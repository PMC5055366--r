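#' Gonadosomatic index
#'
#' Reproductive investment as ovary mass relative to somatic mass:
#' `I_G = 100 * M_O / (M_T - M_O)`.
#'
#' @param total_mass_g Total body mass (g), including the ovary.
#' @param ovary_mass_g Ovary mass (g); must satisfy
#'   `0 <= ovary_mass_g < total_mass_g`.
#' @return Numeric vector of index values.
#' @examples
#' gsi(1100, 100) # 10
#' @export
gsi <- function(total_mass_g, ovary_mass_g) {
  if (any(ovary_mass_g < 0, na.rm = TRUE) ||
      any(ovary_mass_g >= total_mass_g, na.rm = TRUE)) {
    abort("`ovary_mass_g` must satisfy 0 <= ovary_mass_g < total_mass_g.",
          class = "fecundr_domain_error")
  }
  100 * ovary_mass_g / (total_mass_g - ovary_mass_g)
}

#' Add a gonadosomatic-index column to a fish table
#' @param fish A fish tibble (see [table-schemas]).
#' @return `fish` with a `gsi` column.
#' @export
add_gsi <- function(fish) {
  dplyr::mutate(fish, gsi = gsi(.data$total_mass_g, .data$ovary_mass_g))
}

#' Gravimetric determinate estimate of potential annual fecundity
#'
#' Expands phase-resolved cell counts from weighed ovary subsamples to the
#' whole ovary: `PAF = (C_S / M_S) * M_O`, where `C_S` is the count of the
#' advanced cohort (secondary-growth cells, plus transitional-growth cells
#' when `include_transitional = TRUE`) in a subsample of mass `M_S`, and
#' `M_O` is the ovary mass. When a fish has several subsamples their cell
#' densities `C_S / M_S` are averaged before expansion.
#'
#' Early in the run, transitional cells recruit fully and are spawned in
#' the current year, so they are included by default; the attached
#' `gap_uncertainty` (percent of transitional cells among the advanced
#' cohort) is exactly the relative drop in the estimate were they
#' excluded.
#'
#' @param subsamples Tibble in the `subsamples` schema of [table-schemas]
#'   (one or more rows per fish).
#' @param fish Optional fish tibble supplying `ovary_mass_g` (joined by
#'   `fish_id`); alternatively pass `ovary_mass_g` directly.
#' @param ovary_mass_g Optional numeric: ovary mass per subsample row or a
#'   single value, used when `fish` is not given.
#' @param include_transitional Count transitional cells in the advanced
#'   cohort? Default TRUE.
#' @return Tibble with one row per fish: `fish_id, n_subsamples, density`
#'   (advanced cells per gram), `paf`, `gap_uncertainty` (percent),
#'   `include_transitional`. Fish whose advanced-cohort count is zero get
#'   `paf = 0` with a warning.
#' @examples
#' ss <- tibble::tibble(fish_id = "f1", subsample_mass_g = 0.3,
#'                      count_primary = 500, count_transitional = 0,
#'                      count_secondary = 300, count_maturation = 0)
#' determinate_paf(ss, ovary_mass_g = 300) # paf = 300000
#' @export
determinate_paf <- function(subsamples, fish = NULL, ovary_mass_g = NULL,
                            include_transitional = TRUE) {
  check_positive(subsamples$subsample_mass_g, "subsample_mass_g")
  check_positive(subsamples$count_transitional, "count_transitional",
                 strict = FALSE)
  check_positive(subsamples$count_secondary, "count_secondary",
                 strict = FALSE)

  x <- subsamples
  if (!is.null(fish)) {
    x <- dplyr::left_join(
      x, dplyr::select(fish, "fish_id", "ovary_mass_g"), by = "fish_id")
  } else {
    if (is.null(ovary_mass_g)) {
      abort("Supply ovary masses via `fish` or `ovary_mass_g`.",
            class = "fecundr_domain_error")
    }
    x$ovary_mass_g <- ovary_mass_g
  }
  check_positive(x$ovary_mass_g, "ovary_mass_g")

  x$c_s <- x$count_secondary +
    if (include_transitional) x$count_transitional else 0
  out <- x |>
    dplyr::group_by(.data$fish_id) |>
    dplyr::summarise(
      n_subsamples = dplyr::n(),
      density = mean(.data$c_s / .data$subsample_mass_g),
      paf = mean(.data$c_s / .data$subsample_mass_g) * .data$ovary_mass_g[1],
      total_transitional = sum(.data$count_transitional),
      total_secondary = sum(.data$count_secondary),
      .groups = "drop"
    )
  if (any(out$total_transitional + out$total_secondary == 0)) {
    warn("Advanced-cohort count is zero for some fish; their PAF is 0.")
    gu <- suppressWarnings(
      gap_uncertainty(out$total_transitional, out$total_secondary))
  } else {
    gu <- gap_uncertainty(out$total_transitional, out$total_secondary)
  }
  out |>
    dplyr::mutate(gap_uncertainty = gu,
                  include_transitional = include_transitional) |>
    dplyr::select(!dplyr::all_of(c("total_transitional", "total_secondary")))
}

#' Fecundity-size regression on the log-log scale
#'
#' Ordinary least squares of `log10(PAF)` on `log10(L_F)`, fitted
#' separately per sampling group, with the correlation coefficient and its
#' two-sided significance probability — the standard allometric summary
#' of a fecundity-at-length panel.
#'
#' @param data Tibble with a length column, a PAF column and (optionally) a
#'   grouping column.
#' @param length_col,paf_col,group_col Column names (strings). With
#'   `group_col = NULL` a single pooled fit is returned.
#' @return A `fecundity_regression` object: per-group tibble of
#'   `slope, intercept, r, n, p_value` (log10-log10 scale) with the lm
#'   fits stored in a list column. Groups need `n >= 3` and strictly
#'   positive values.
#' @export
fecundity_size_regression <- function(data, length_col = "fork_length_mm",
                                      paf_col = "paf", group_col = NULL) {
  x <- tibble(
    l = data[[length_col]], f = data[[paf_col]],
    group = if (is.null(group_col)) "all" else as.character(data[[group_col]])
  )
  if (any(x$l <= 0 | x$f <= 0, na.rm = TRUE)) {
    abort("Lengths and fecundities must be > 0 for log transformation.",
          class = "fecundr_domain_error")
  }
  x <- x[complete.cases(x), ]
  fits <- x |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3) {
        abort(sprintf("Group `%s` has fewer than 3 complete rows.",
                      key$group[1]), class = "fecundr_domain_error")
      }
      fit <- lm(log10(f) ~ log10(l), data = d)
      ct <- summary(fit)$coefficients
      tibble(
        slope = ct[2, 1], intercept = ct[1, 1],
        r = sign(ct[2, 1]) * sqrt(summary(fit)$r.squared),
        n = nrow(d),
        p_value = ct[2, 4],
        fit = list(fit)
      )
    }) |>
    dplyr::ungroup()
  structure(fits, class = c("fecundity_regression", class(fits)))
}

#' @export
print.fecundity_regression <- function(x, ...) {
  cat("log10(PAF) ~ log10(length), per group:\n")
  print(dplyr::select(as_tibble(x), !"fit"), ...)
  invisible(x)
}

#' @rdname fecundity_size_regression
#' @param x,object A `fecundity_regression`.
#' @param ... Unused.
#' @export
tidy.fecundity_regression <- function(x, ...) {
  dplyr::select(as_tibble(x), !"fit")
}

#' Test for the early-spawning decline of the yolked standing crop
#'
#' Analysis of covariance of `log10(PAF)` on `log10(L_F)` across sampling
#' groups. A determinate fecundity pattern predicts that the standing crop
#' of yolked oocytes — and hence size-specific PAF — drops as soon as
#' females begin spawning, so spawning groups should sit significantly
#' below the pre-spawning baseline at a common slope.
#'
#' The size-by-group interaction is tested first; when no interaction is
#' significant at `alpha`, the model is reduced to main effects and each
#' group is contrasted against the pooled pre-spawning baseline (and the
#' pre-spawning groups against each other), via estimated marginal means.
#' No multiplicity correction is applied to the contrasts.
#'
#' @param data Tibble with length, PAF and group columns.
#' @param pre_groups Character vector naming the pre-spawning (baseline)
#'   groups; defaults to all groups whose label starts with "pre".
#' @param alpha Significance threshold for dropping the interaction,
#'   default 0.05.
#' @inheritParams fecundity_size_regression
#' @return A `decline_ancova` object with elements `interaction_p`,
#'   `p_size`, `p_group` (main-effect probabilities), `contrasts`
#'   (tibble: contrast, estimate on the log10 scale, SE, t, p_value),
#'   `model` (the reduced or full lm) and `n`.
#' @export
decline_ancova <- function(data, length_col = "fork_length_mm",
                           paf_col = "paf", group_col = "group",
                           pre_groups = NULL, alpha = 0.05) {
  x <- tibble(
    log_l = log10(data[[length_col]]),
    log_f = log10(data[[paf_col]]),
    group = factor(data[[group_col]])
  )
  x <- x[complete.cases(x), ]
  lev <- levels(droplevels(x$group))
  x$group <- droplevels(x$group)
  if (length(lev) < 2) {
    abort("ANCOVA needs at least two groups.", class = "fecundr_domain_error")
  }
  if (any(table(x$group) < 3)) {
    abort("Each group needs at least 3 rows.", class = "fecundr_domain_error")
  }
  pre_groups <- pre_groups %||% grep("^pre", lev, value = TRUE)
  if (length(pre_groups) == 0) {
    abort("No pre-spawning baseline group identified; set `pre_groups`.",
          class = "fecundr_domain_error")
  }

  full <- lm(log_f ~ log_l * group, data = x)
  if (anyNA(coef(full))) {
    abort("Singular design: a group has no size spread on the log scale.",
          class = "fecundr_domain_error")
  }
  a_full <- anova(full)
  interaction_p <- a_full[["Pr(>F)"]][rownames(a_full) == "log_l:group"]

  reduced <- interaction_p >= alpha
  model <- if (reduced) lm(log_f ~ log_l + group, data = x) else full
  a_main <- anova(model)
  p_size <- a_main[["Pr(>F)"]][rownames(a_main) == "log_l"]
  p_group <- a_main[["Pr(>F)"]][rownames(a_main) == "group"]

  # contrasts vs the pooled pre-spawning baseline, at the mean covariate
  emm <- suppressMessages(emmeans::emmeans(model, "group"))
  w_pre <- as.numeric(lev %in% pre_groups) / sum(lev %in% pre_groups)
  spawn_groups <- setdiff(lev, pre_groups)
  clist <- list()
  for (g in spawn_groups) {
    clist[[paste0(g, " - pre_spawning")]] <-
      as.numeric(lev == g) - w_pre
  }
  if (length(spawn_groups) > 1) {
    # the headline contrast: all spawning groups pooled vs the baseline
    clist[["spawning - pre_spawning"]] <-
      as.numeric(lev %in% spawn_groups) / length(spawn_groups) - w_pre
  }
  if (length(pre_groups) == 2) {
    clist[[paste(pre_groups[2], "-", pre_groups[1])]] <-
      as.numeric(lev == pre_groups[2]) - as.numeric(lev == pre_groups[1])
  }
  ctr <- suppressMessages(
    as.data.frame(emmeans::contrast(emm, clist, adjust = "none")))
  contrasts <- tibble(
    contrast = ctr$contrast, estimate = ctr$estimate, se = ctr$SE,
    t = ctr$t.ratio, p_value = ctr$p.value
  )

  structure(list(
    interaction_p = interaction_p, interaction_dropped = reduced,
    p_size = p_size, p_group = p_group, contrasts = contrasts,
    model = model, n = nrow(x), alpha = alpha, pre_groups = pre_groups
  ), class = "decline_ancova")
}

#' @export
print.decline_ancova <- function(x, ...) {
  cat("ANCOVA: log10(PAF) ~ log10(length) ",
      if (x$interaction_dropped) "+" else "*", " group\n", sep = "")
  cat(sprintf("  interaction P = %.4g (%s at alpha = %g)\n",
              x$interaction_p,
              if (x$interaction_dropped) "dropped" else "kept", x$alpha))
  cat(sprintf("  main effects: size P = %.4g, group P = %.4g, n = %d\n",
              x$p_size, x$p_group, x$n))
  cat("  contrasts vs pooled pre-spawning baseline (log10 scale):\n")
  print(x$contrasts, ...)
  invisible(x)
}

#' @rdname decline_ancova
#' @param x,object A `decline_ancova` object.
#' @param ... Unused.
#' @export
tidy.decline_ancova <- function(x, ...) x$contrasts

#' @rdname decline_ancova
#' @export
glance.decline_ancova <- function(x, ...) {
  tibble(
    interaction_p = x$interaction_p,
    interaction_dropped = x$interaction_dropped,
    p_size = x$p_size, p_group = x$p_group,
    r_squared = summary(x$model)$r.squared, n = x$n
  )
}
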