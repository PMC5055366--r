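#' Configuration for the synthetic oogenesis / population generator
#'
#' Defines a spawning run of batch-spawning females with fully known
#' ground truth, under either of the two canonical modes of yolked-oocyte
#' development:
#'
#' * `group_synchronous` — the advanced (yolked) cohort is fixed at entry;
#'   true annual fecundity equals the initial standing crop, which is
#'   non-increasing once spawning begins. De novo recruitment must be 0.
#' * `asynchronous` — new yolked oocytes recruit throughout the run
#'   (de novo vitellogenesis) at `de_novo_rate` x initial crop per day;
#'   true annual fecundity is the initial crop plus total recruitment, so
#'   a standing-crop (determinate) census underestimates it.
#'
#' Each fish receives a fork length, an entry date, a true spawning
#' interval and residence time, and a spawning schedule (one batch every
#' SI days over RT days, even split of the true fecundity across
#' batches). Day-adjusted histology markers, gravimetric subsamples with
#' binomial-thinning counts, and whole-oocyte diameter measurements are
#' emitted in exactly the pipeline's table schemas.
#'
#' @param mode `"group_synchronous"` or `"asynchronous"`.
#' @param n_fish Number of females.
#' @param run_start Date the first females enter the river.
#' @param entry_spread_days Entry dates are uniform on
#'   `run_start + 0:entry_spread_days`.
#' @param length_mean,length_sd,length_range Fork-length distribution
#'   (mm), truncated normal.
#' @param fec_log10_intercept,fec_log10_slope,fec_sdlog10 True
#'   fecundity-length relation:
#'   `log10(crop) = intercept + slope * log10(L_F) + N(0, sdlog10)`.
#' @param si_mean,si_sd True spawning-interval distribution (days),
#'   normal truncated at 1 (a female cannot spawn twice per day).
#' @param rt_mean,rt_sd True residence-time distribution (days), normal
#'   truncated at 2.
#' @param de_novo_rate Daily de novo recruitment as a fraction of the
#'   initial crop; must be 0 in `group_synchronous` mode. (At the default
#'   asynchronous value 1/30 and a ~30 d residence, total recruitment
#'   roughly equals the initial crop.)
#' @param transitional_frac_entry Fraction of the advanced crop still in
#'   the transitional phase at entry (group-synchronous mode), declining
#'   linearly to 0 over `recruitment_days`.
#' @param recruitment_days Days after entry by which recruitment of the
#'   advanced cohort completes (group-synchronous mode).
#' @param transitional_transit_days Days a recruiting oocyte spends in
#'   the transitional window (asynchronous mode); the standing
#'   transitional pool is `de_novo_rate * transit * initial crop`, the
#'   steady-state occupancy of the recruitment pipeline.
#' @param atresia_fraction Fraction of the initial crop remaining,
#'   atretic, in spent females.
#' @param phase_diameters Named list of `c(mean, sd, min, max)` diameter
#'   parameters (um) per phase for whole-oocyte measurements.
#' @param primary_reservoir Size of the previtellogenic reservoir as a
#'   multiple of the initial crop.
#' @param mass_per_oocyte_g Ovary mass per advanced oocyte (g).
#' @param stroma_frac Ovarian stromal mass as a fraction of the initial
#'   crop mass.
#' @param condition_g_mm3 Somatic mass coefficient: soma = coef * L_F^3.
#' @param subsample_mass_range Gravimetric subsample mass (g), uniform.
#' @param n_oocytes_measured Whole-oocyte diameters measured per profiled
#'   fish.
#' @param measurement_floor Diameter floor (um) of the imaging workflow.
#' @param gap_band Diameter band (um) used for size-gap diagnostics.
#' @param sampling_dates,n_per_date Default survey design (days after
#'   `run_start`, fish per date) used by [generate_population()].
#' @param seed Non-negative integer; all randomness flows from it.
#' @return A validated `synthetic_config` object.
#' @export
synthetic_config <- function(mode = c("group_synchronous", "asynchronous"),
                             n_fish = 150,
                             run_start = as.Date("2015-04-30"),
                             entry_spread_days = 5,
                             length_mean = 460, length_sd = 30,
                             length_range = c(396, 528),
                             fec_log10_intercept = -2.48,
                             fec_log10_slope = 3.0,
                             fec_sdlog10 = 0.105,
                             si_mean = 4.83, si_sd = 1.40,
                             rt_mean = 30.0, rt_sd = 2.6,
                             de_novo_rate = if (match.arg(mode) ==
                               "asynchronous") 1 / 30 else 0,
                             transitional_frac_entry = 0.04,
                             recruitment_days = 10,
                             transitional_transit_days = 5,
                             atresia_fraction = 0.02,
                             phase_diameters = list(
                               primary = c(150, 50, 40, 299),
                               transitional = c(400, 40, 300, 499),
                               secondary = c(900, 180, 520, 1480),
                               maturation = c(1600, 120, 1250, 1950)),
                             primary_reservoir = 3,
                             mass_per_oocyte_g = 0.001,
                             stroma_frac = 0.1,
                             condition_g_mm3 = 1.65e-5,
                             subsample_mass_range = c(0.2, 0.55),
                             n_oocytes_measured = 400,
                             measurement_floor = 100,
                             gap_band = c(300, 500),
                             sampling_dates = seq(12, 33, by = 7),
                             n_per_date = 30,
                             seed = 1) {
  mode <- match.arg(mode)
  cfg <- as.list(environment())
  if (mode == "group_synchronous" && cfg$de_novo_rate != 0) {
    abort("de_novo_rate must be 0 in group_synchronous mode.",
          class = "fecundr_domain_error")
  }
  check_positive(cfg$n_fish, "n_fish")
  check_positive(cfg$si_mean, "si_mean")
  check_positive(cfg$rt_mean, "rt_mean")
  if (cfg$de_novo_rate < 0 || cfg$atresia_fraction < 0 ||
      cfg$atresia_fraction > 1 ||
      cfg$transitional_frac_entry < 0 || cfg$transitional_frac_entry > 1) {
    abort("Rates and fractions must lie in [0, 1].",
          class = "fecundr_domain_error")
  }
  if (cfg$seed < 0 || cfg$seed != round(cfg$seed)) {
    abort("`seed` must be a non-negative integer.",
          class = "fecundr_domain_error")
  }
  structure(cfg, class = "synthetic_config")
}

rtruncnorm_ <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

#' Generate a synthetic spawning population with known truth
#'
#' Realizes the per-fish ground truth (lengths, crops, spawning
#' schedules) of a [synthetic_config()] and runs the default survey
#' design over it, emitting the four pipeline tables. Identical
#' configurations (including the seed) regenerate bit-identical output.
#'
#' @param config A `synthetic_config`.
#' @return A `synthetic_population` list: `config`; `truth` (tibble of
#'   per-fish true annual fecundity, initial crop, SI, RT, entry date,
#'   spawn dates, batch size); and `survey` — a list of `fish`,
#'   `oocytes`, `subsamples`, `markers` tibbles from the default design
#'   (see [sample_run()] for custom designs).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  cfg <- config
  n <- cfg$n_fish

  len <- rtruncnorm_(n, cfg$length_mean, cfg$length_sd,
                     cfg$length_range[1], cfg$length_range[2])
  crop0 <- round(10^(cfg$fec_log10_intercept +
                       cfg$fec_log10_slope * log10(len) +
                       rnorm(n, 0, cfg$fec_sdlog10)))
  si <- rtruncnorm_(n, cfg$si_mean, cfg$si_sd, lower = 1)
  rt <- rtruncnorm_(n, cfg$rt_mean, cfg$rt_sd, lower = 2)
  entry <- cfg$run_start + sample.int(cfg$entry_spread_days + 1, n,
                                      replace = TRUE) - 1L

  single <- si > rt
  if (any(single)) {
    warn(sprintf(
      "%d fish have SI > RT and spawn only once.", sum(single)))
  }
  spawn_dates <- purrr::map(seq_len(n), function(i) {
    first <- 2 + floor(runif(1) * si[i])
    offs <- unique(round(seq(first, by = si[i],
                             length.out = max(1, ceiling(rt[i] / si[i])))))
    offs <- offs[offs <= rt[i]]
    if (!length(offs)) offs <- first
    entry[i] + offs
  })
  n_batches <- lengths(spawn_dates)
  true_fec <- crop0 * (1 + cfg$de_novo_rate * rt)
  batch_size <- true_fec / n_batches

  truth <- tibble(
    fish_id = sprintf("syn%04d", seq_len(n)),
    fork_length_mm = round(len),
    initial_crop = crop0,
    true_fecundity = true_fec,
    si = si, rt = rt,
    entry = entry,
    n_batches = n_batches,
    batch_size = batch_size,
    spawn_dates = spawn_dates
  )
  pop <- structure(list(config = cfg, truth = truth),
                   class = "synthetic_population")
  pop$survey <- sample_run(pop, dates = cfg$run_start + cfg$sampling_dates,
                           n_per_date = cfg$n_per_date, reseed = FALSE)
  pop
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat(sprintf(
    "<synthetic_population> %d fish, %s mode, seed %d\n",
    x$config$n_fish, x$config$mode, x$config$seed))
  cat(sprintf("  mean true fecundity %s; SI %.2f d; RT %.1f d\n",
              format(round(mean(x$truth$true_fecundity))),
              mean(x$truth$si), mean(x$truth$rt)))
  invisible(x)
}

# per-fish ovary state on a given date (vectorized over fish)
ovary_state <- function(pop, idx, date) {
  cfg <- pop$config
  tr <- pop$truth[idx, ]
  n <- nrow(tr)
  days_in <- as.numeric(date - tr$entry)

  s0 <- t_next <- rep(NA_real_, n)
  spawned_k <- integer(n)
  for (i in seq_len(n)) {
    ev <- as.numeric(tr$spawn_dates[[i]] - date)
    spawned_k[i] <- sum(ev <= 0)
    if (any(ev <= 0)) s0[i] <- -max(ev[ev <= 0])
    if (any(ev > 0)) t_next[i] <- min(ev[ev > 0])
  }
  done <- spawned_k == tr$n_batches

  recruited <- tr$initial_crop *
    (1 + cfg$de_novo_rate * pmax(0, pmin(days_in, tr$rt)))
  crop <- pmax(recruited - spawned_k * tr$batch_size,
               ifelse(done, cfg$atresia_fraction * tr$initial_crop, 0))

  hydrated <- ifelse(!done & !is.na(t_next) & t_next == 1,
                     pmin(tr$batch_size, crop), 0)
  transitional <- if (cfg$mode == "group_synchronous") {
    tf <- cfg$transitional_frac_entry *
      pmax(0, 1 - days_in / cfg$recruitment_days)
    round(tf * (crop - hydrated))
  } else {
    # steady-state occupancy of the de novo recruitment pipeline
    pmin(round(cfg$de_novo_rate * cfg$transitional_transit_days *
                 tr$initial_crop),
         pmax(round(crop - hydrated), 0))
  }
  secondary <- pmax(round(crop - hydrated - transitional), 0)
  maturation <- round(hydrated)
  primary <- round(cfg$primary_reservoir * tr$initial_crop)

  maos <- dplyr::case_when(
    !done & !is.na(t_next) & t_next == 1 ~ "NM1",
    !is.na(s0) & s0 == 0 ~ sample(c("NM2", "NM3", "H"), n, replace = TRUE),
    secondary > 0 ~ "V2",
    transitional > 0 ~ "C2",
    TRUE ~ "PE"
  )
  pof_age <- dplyr::case_when(
    is.na(s0) ~ "none",
    s0 == 0 ~ "POF0", s0 == 1 ~ "POF1", s0 == 2 ~ "POF2",
    TRUE ~ "none"
  )
  macro_class <- dplyr::case_when(
    done ~ "E",
    maturation > 0 ~ "B",
    !is.na(s0) & s0 == 0 ~ "C",
    spawned_k > 0 ~ "D",
    TRUE ~ "A"
  )

  ovary_mass <- cfg$mass_per_oocyte_g *
    (crop + cfg$stroma_frac * tr$initial_crop)
  soma <- cfg$condition_g_mm3 * tr$fork_length_mm^3
  tibble(
    fish_id = tr$fish_id, date = date,
    fork_length_mm = tr$fork_length_mm,
    total_mass_g = round(soma + ovary_mass, 1),
    ovary_mass_g = round(ovary_mass, 3),
    macro_class = macro_class, maos = maos, pof_age = pof_age,
    n_primary = primary, n_transitional = transitional,
    n_secondary = secondary, n_maturation = maturation
  )
}

draw_subsample <- function(state, cfg) {
  n <- nrow(state)
  m_s <- runif(n, cfg$subsample_mass_range[1], cfg$subsample_mass_range[2])
  p <- pmin(m_s / state$ovary_mass_g, 1)
  tibble(
    fish_id = state$fish_id,
    subsample_mass_g = round(m_s, 4),
    count_primary = rbinom(n, state$n_primary, p),
    count_transitional = rbinom(n, state$n_transitional, p),
    count_secondary = rbinom(n, state$n_secondary, p),
    count_maturation = rbinom(n, state$n_maturation, p)
  )
}

draw_oocytes <- function(state, cfg) {
  purrr::map_dfr(seq_len(nrow(state)), function(i) {
    counts <- c(primary = state$n_primary[i],
                transitional = state$n_transitional[i],
                secondary = state$n_secondary[i],
                maturation = state$n_maturation[i])
    if (sum(counts) == 0) {
      return(tibble(fish_id = character(), diameter_um = numeric(),
                    phase = character(), histology_stage = character()))
    }
    k <- stats::rmultinom(1, cfg$n_oocytes_measured,
                          counts / sum(counts))[, 1]
    phase <- rep(names(counts), k)
    d <- unlist(purrr::map2(names(counts), k, function(ph, m) {
      pd <- cfg$phase_diameters[[ph]]
      rtruncnorm_(m, pd[1], pd[2], pd[3], pd[4])
    }), use.names = FALSE)
    tibble(fish_id = state$fish_id[i], diameter_um = round(d, 1),
           phase = phase, histology_stage = NA_character_)
  })
}

#' Survey a synthetic population
#'
#' Samples fish (destructively, without replacement across dates) on a
#' set of survey dates and emits observed tables in the pipeline schemas:
#' fish records with masses and histology markers, one gravimetric
#' subsample per fish (binomial-thinning counts), whole-oocyte diameter
#' measurements, and the per-date marker aggregation.
#'
#' Special designs: `when = "entry"` censuses every fish on its own entry
#' date (a pre-spawning census: spawning starts no earlier than two days
#' after entry), and `when = "end"` censuses every fish the day after its
#' residence ends (spent females with only the atretic residue of the
#' crop).
#'
#' @param pop A `synthetic_population`.
#' @param dates Survey dates (used when `when = "dates"`).
#' @param n_per_date Fish sampled per survey date.
#' @param when `"dates"` (default), `"entry"` or `"end"`.
#' @param site Site label stamped on the records.
#' @param reseed Reset the RNG from the population's seed (offset so the
#'   survey does not replay the generator's stream)? Default TRUE, making
#'   any survey of a given population reproducible in isolation.
#' @return List of tibbles `fish`, `oocytes`, `subsamples`, `markers`.
#' @export
sample_run <- function(pop, dates = NULL, n_per_date = 30,
                       when = c("dates", "entry", "end"),
                       site = "synthetic", reseed = TRUE) {
  stopifnot(inherits(pop, "synthetic_population"))
  when <- match.arg(when)
  cfg <- pop$config
  if (reseed) set.seed(cfg$seed + 1000003L)

  states <- list()
  if (when == "entry") {
    for (d in split(seq_len(nrow(pop$truth)), pop$truth$entry)) {
      states[[length(states) + 1]] <-
        ovary_state(pop, d, pop$truth$entry[d[1]])
    }
  } else if (when == "end") {
    end_date <- pop$truth$entry + ceiling(pop$truth$rt) + 1
    for (d in split(seq_len(nrow(pop$truth)), end_date)) {
      states[[length(states) + 1]] <- ovary_state(pop, d, end_date[d[1]])
    }
  } else {
    if (is.null(dates)) {
      abort("Supply `dates` for a dated survey.",
            class = "fecundr_domain_error")
    }
    pool <- seq_len(nrow(pop$truth))
    for (dd in seq_along(dates)) {
      d <- dates[dd]
      avail <- pool[pop$truth$entry[pool] <= d &
                      d <= pop$truth$entry[pool] +
                      ceiling(pop$truth$rt[pool]) + 2]
      if (!length(avail)) {
        warn(sprintf("No fish available on %s; empty sample.",
                     format(d)))
        next
      }
      take <- if (length(avail) > n_per_date) {
        sample(avail, n_per_date)
      } else {
        avail
      }
      pool <- setdiff(pool, take)
      states[[length(states) + 1]] <- ovary_state(pop, take, d)
    }
  }
  state <- dplyr::bind_rows(states)
  if (nrow(state) == 0) {
    abort("Survey produced no samples.", class = "fecundr_domain_error")
  }

  fish <- state |>
    dplyr::transmute(
      fish_id = .data$fish_id, date = .data$date, site = site,
      fork_length_mm = .data$fork_length_mm,
      total_mass_g = .data$total_mass_g,
      ovary_mass_g = .data$ovary_mass_g,
      age_yr = NA_integer_,
      macro_class = .data$macro_class, maos = .data$maos,
      pof_age = .data$pof_age
    )
  subsamples <- draw_subsample(state, cfg)
  oocytes <- draw_oocytes(state, cfg)
  markers <- marker_proportions(fish)
  list(fish = fish, oocytes = oocytes, subsamples = subsamples,
       markers = markers)
}
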