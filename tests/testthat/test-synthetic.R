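gen_quiet <- function(cfg) {
  suppressMessages(suppressWarnings(generate_population(cfg)))
}

test_that("a fixed seed regenerates the population bit-identically", {
  cfg <- synthetic_config(n_fish = 30, seed = 12, sampling_dates = c(12, 19),
                          n_per_date = 15)
  a <- gen_quiet(cfg)
  b <- gen_quiet(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$survey, b$survey)
})

test_that("ground truth honours the synchrony mode", {
  cfg <- synthetic_config(n_fish = 25, seed = 13, sampling_dates = 14,
                          n_per_date = 10)
  pop <- gen_quiet(cfg)
  # group synchrony: annual fecundity IS the initial standing crop
  expect_equal(pop$truth$true_fecundity, pop$truth$initial_crop)

  cfg2 <- synthetic_config(mode = "asynchronous", n_fish = 25, seed = 13,
                           sampling_dates = 14, n_per_date = 10)
  pop2 <- gen_quiet(cfg2)
  # asynchrony: initial crop + de novo recruitment over the residence
  expect_equal(pop2$truth$true_fecundity,
               pop2$truth$initial_crop *
                 (1 + cfg2$de_novo_rate * pop2$truth$rt))
  expect_true(all(pop2$truth$true_fecundity > pop2$truth$initial_crop))

  expect_error(synthetic_config(mode = "group_synchronous",
                                de_novo_rate = 0.05),
               class = "fecundr_domain_error")
})

test_that("the advanced crop never grows once spawning begins (synchrony)", {
  cfg <- synthetic_config(n_fish = 3, seed = 14, sampling_dates = 12,
                          n_per_date = 3)
  pop <- gen_quiet(cfg)
  for (i in 1:3) {
    days <- pop$truth$entry[i] + 0:40
    crop <- purrr::map_dbl(days, function(d) {
      st <- fecundr:::ovary_state(pop, i, d)
      st$n_transitional + st$n_secondary + st$n_maturation
    })
    expect_true(all(diff(crop) <= 0))
    # and it starts at the initial crop
    expect_equal(crop[1], pop$truth$initial_crop[i], tolerance = 1e-6)
  }
})

test_that("an entry census is an all-pre-spawning sample", {
  cfg <- synthetic_config(n_fish = 40, seed = 15, sampling_dates = 12,
                          n_per_date = 40)
  pop <- gen_quiet(cfg)
  cen <- sample_run(pop, when = "entry")
  expect_equal(nrow(cen$fish), 40)
  expect_true(all(cen$fish$pof_age == "none"))
  expect_true(all(cen$fish$macro_class == "A"))
  expect_true(all(classify_spawn_status(cen$fish$pof_age) ==
                    "pre_spawning"))
})

test_that("an end-of-run census leaves only the atretic residue", {
  cfg <- synthetic_config(n_fish = 30, seed = 16, sampling_dates = 12,
                          n_per_date = 30)
  pop <- gen_quiet(cfg)
  endc <- sample_run(pop, when = "end")
  expect_true(all(endc$fish$macro_class == "E"))
  expect_true(all(endc$fish$pof_age %in% c("none", "POF0", "POF1", "POF2")))
  est <- determinate_paf(endc$subsamples, fish = endc$fish)
  resid <- dplyr::inner_join(est, pop$truth, by = "fish_id")
  ratio <- resid$paf / resid$initial_crop
  # remaining yolked cells stay near the configured atresia fraction
  expect_lt(mean(ratio), cfg$atresia_fraction * 2)
})

test_that("marker tables equal a direct recount of individual fish", {
  cfg <- synthetic_config(n_fish = 60, seed = 17,
                          sampling_dates = c(12, 19), n_per_date = 30)
  pop <- gen_quiet(cfg)
  fish <- pop$survey$fish
  m <- pop$survey$markers
  for (k in seq_len(nrow(m))) {
    sub <- fish[fish$date == m$date[k], ]
    expect_equal(m$n_females[k], nrow(sub))
    expect_equal(m$p_day_minus1[k], sum(sub$maos == "NM1") / nrow(sub))
    expect_equal(m$p_day0[k],
                 sum(sub$maos %in% c("NM2", "NM3", "H") |
                       sub$pof_age == "POF0") / nrow(sub))
    expect_equal(m$p_day_plus1[k], sum(sub$pof_age == "POF1") / nrow(sub))
    expect_equal(m$p_day_plus2[k], sum(sub$pof_age == "POF2") / nrow(sub))
  }
})

test_that("infeasible schedules (SI > RT) degrade to a single spawning", {
  expect_warning(
    generate_population(
      synthetic_config(n_fish = 10, seed = 18, si_mean = 40, si_sd = 1,
                       rt_mean = 10, rt_sd = 1, sampling_dates = 5,
                       n_per_date = 5)),
    "spawn only once")
})

test_that("the determinate estimator recovers true fecundity (synchrony)", {
  cfg <- synthetic_config(n_fish = 50, seed = 19, sampling_dates = 12,
                          n_per_date = 50)
  pop <- gen_quiet(cfg)
  cen <- sample_run(pop, when = "entry")
  est <- determinate_paf(cen$subsamples, fish = cen$fish)
  d <- dplyr::inner_join(est, pop$truth, by = "fish_id")
  bias <- mean(d$paf / d$true_fecundity) - 1
  expect_lt(abs(bias), 0.02)
})

test_that("spawning metrics recover the true spawning interval", {
  cfg <- synthetic_config(n_fish = 150, seed = 20)
  pop <- gen_quiet(cfg)
  # exclude spent females, as a field protocol would (down-running fish
  # no longer carry spawning markers and inflate the apparent interval)
  fish <- pop$survey$fish[pop$survey$fish$macro_class != "E", ]
  st <- si_table(marker_proportions(fish))
  rec <- pooled_si_summary(st)$mean_si
  expect_lt(abs(rec / mean(pop$truth$si) - 1), 0.15)
})

test_that("the indeterminate route recovers mean fecundity within 10%", {
  cfg <- synthetic_config(n_fish = 150, seed = 21)
  pop <- gen_quiet(cfg)
  fish <- pop$survey$fish[pop$survey$fish$macro_class != "E", ]
  st <- si_table(marker_proportions(fish))
  si_spec <- fit_si(st$si[!is.na(st$si)])
  rt_spec <- fit_rt(cfg$rt_mean, cfg$rt_sd)
  # batch fecundity from hydrated females' gravimetric counts
  hyd <- dplyr::inner_join(pop$survey$subsamples, pop$survey$fish,
                           by = "fish_id") |>
    dplyr::filter(count_maturation > 0)
  bf_vals <- hyd$count_maturation / hyd$subsample_mass_g * hyd$ovary_mass_g
  bf_spec <- fit_bf(values = bf_vals)
  sim <- suppressMessages(
    simulate_paf(rt_spec, si_spec, bf_spec, n_draws = 1000,
                 n_replicates = 200, seed = 22))
  truth <- mean(pop$truth$true_fecundity)
  expect_lt(abs(glance(sim)$grand_mean / truth - 1), 0.10)
})

test_that("asynchrony splits the two methods: determinate ~ half of truth", {
  cfg <- synthetic_config(mode = "asynchronous", n_fish = 150, seed = 23)
  pop <- gen_quiet(cfg)
  truth <- mean(pop$truth$true_fecundity)

  # determinate census of the pre-spawning standing crop
  cen <- sample_run(pop, when = "entry")
  est <- determinate_paf(cen$subsamples, fish = cen$fish)
  d <- dplyr::inner_join(est, pop$truth, by = "fish_id")
  ratio <- mean(d$paf / d$true_fecundity)
  expect_lt(abs(ratio - 0.5), 0.05)

  # the indeterminate route tracks the full (replenished) production
  fish <- pop$survey$fish[pop$survey$fish$macro_class != "E", ]
  st <- si_table(marker_proportions(fish))
  hyd <- dplyr::inner_join(pop$survey$subsamples, pop$survey$fish,
                           by = "fish_id") |>
    dplyr::filter(count_maturation > 0)
  bf_vals <- hyd$count_maturation / hyd$subsample_mass_g * hyd$ovary_mass_g
  sim <- suppressMessages(
    simulate_paf(fit_rt(cfg$rt_mean, cfg$rt_sd),
                 fit_si(st$si[!is.na(st$si)]), fit_bf(values = bf_vals),
                 n_draws = 1000, n_replicates = 200, seed = 24))
  expect_lt(abs(glance(sim)$grand_mean / truth - 1), 0.10)
})
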