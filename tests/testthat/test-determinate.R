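test_that("gonadosomatic index follows its defining ratio", {
  expect_equal(gsi(1100, 100), 10)
  expect_equal(gsi(1500, 0), 0)
  expect_equal(gsi(1500, 265.4), 100 * 265.4 / (1500 - 265.4))
  expect_error(gsi(1000, 1200), class = "fecundr_domain_error")
  expect_error(gsi(1000, -1), class = "fecundr_domain_error")
  fish <- make_fish(2)
  expect_equal(add_gsi(fish)$gsi,
               100 * fish$ovary_mass_g /
                 (fish$total_mass_g - fish$ovary_mass_g))
})

test_that("gravimetric expansion gives PAF = C_S/M_S * M_O", {
  expect_equal(determinate_paf(make_subsample(mass = 0.3, s = 300),
                               ovary_mass_g = 300)$paf, 300000)

  ss <- make_subsample(mass = 0.2, t = 8, s = 92)
  with_t <- determinate_paf(ss, ovary_mass_g = 200,
                            include_transitional = TRUE)
  no_t <- determinate_paf(ss, ovary_mass_g = 200,
                          include_transitional = FALSE)
  expect_equal(with_t$paf, 100000)
  expect_equal(no_t$paf, 92000)
  expect_equal(with_t$gap_uncertainty, 8)
  # the relative drop from excluding transitionals equals gap uncertainty
  expect_equal(no_t$paf, with_t$paf * (1 - with_t$gap_uncertainty / 100))

  expect_warning(z <- determinate_paf(make_subsample(t = 0, s = 0),
                                      ovary_mass_g = 100))
  expect_equal(z$paf, 0)
  expect_error(determinate_paf(make_subsample(mass = -1),
                               ovary_mass_g = 1),
               class = "fecundr_domain_error")
})

test_that("PAF is homogeneous in ovary mass and counts; densities average", {
  ss <- make_subsample(mass = 0.25, t = 10, s = 240)
  base <- determinate_paf(ss, ovary_mass_g = 200)$paf
  for (k in c(2, 5)) {
    expect_equal(determinate_paf(ss, ovary_mass_g = 200 * k)$paf, base * k)
    kss <- dplyr::mutate(ss, count_transitional = count_transitional * k,
                         count_secondary = count_secondary * k)
    expect_equal(determinate_paf(kss, ovary_mass_g = 200)$paf, base * k)
  }
  # two subsamples of one fish: mean of densities, not pooled ratio
  two <- dplyr::bind_rows(make_subsample(mass = 0.2, s = 100),
                          make_subsample(mass = 0.4, s = 300))
  est <- determinate_paf(two, ovary_mass_g = 100)
  expect_equal(est$n_subsamples, 2L)
  expect_equal(est$paf, mean(c(100 / 0.2, 300 / 0.4)) * 100)
})

test_that("log-log regression matches the closed-form OLS oracle", {
  # exactly collinear points have r = 1
  d <- tibble::tibble(fork_length_mm = c(400, 450, 500),
                      paf = 10^(-2 + 3 * log10(c(400, 450, 500))))
  fr <- suppressWarnings(tidy(fecundity_size_regression(d)))
  expect_equal(fr$r, 1)
  expect_equal(fr$slope, 3)

  # three hand-computable points vs the closed form, to 1e-10
  d2 <- tibble::tibble(fork_length_mm = c(410, 455, 520),
                       paf = c(210000, 350000, 280000))
  fr2 <- tidy(fecundity_size_regression(d2))
  oracle <- ols_oracle(log10(d2$fork_length_mm), log10(d2$paf))
  expect_equal(fr2$slope, oracle$slope, tolerance = 1e-10)
  expect_equal(fr2$intercept, oracle$intercept, tolerance = 1e-10)
  expect_equal(fr2$r, oracle$r, tolerance = 1e-10)
  expect_equal(fr2$p_value, oracle$p_value, tolerance = 1e-10)

  expect_error(fecundity_size_regression(
    tibble::tibble(fork_length_mm = c(400, 410, 420),
                   paf = c(1000, -5, 2000))),
    class = "fecundr_domain_error")
  expect_error(fecundity_size_regression(d2[1:2, ]),
               class = "fecundr_domain_error")
})

test_that("regression recovers a known log-log slope within 2 SE", {
  set.seed(31)
  l <- runif(40, 400, 520)
  f <- 10^(-2.5 + 3.1 * log10(l) + rnorm(40, 0, 0.1))
  fit <- tidy(fecundity_size_regression(
    tibble::tibble(fork_length_mm = l, paf = f)))
  se <- summary(fecundity_size_regression(
    tibble::tibble(fork_length_mm = l, paf = f))$fit[[1]])$coefficients[2, 2]
  expect_lt(abs(fit$slope - 3.1), 2 * se)
})

test_that("ANCOVA finds no group effect between identical groups", {
  set.seed(41)
  base <- tibble::tibble(
    fork_length_mm = runif(25, 400, 520),
    paf = 10^(-2.5 + 3 * log10(fork_length_mm) + rnorm(25, 0, 0.1))
  )
  d <- dplyr::bind_rows(
    dplyr::mutate(base, group = "pre_spawning_a"),
    dplyr::mutate(base, group = "spawning_b")
  )
  an <- decline_ancova(d)
  expect_gt(an$p_group, 0.9)
  expect_equal(tidy(an)$estimate[1], 0, tolerance = 1e-12)
})

test_that("ANCOVA detects a -0.1 log10 spawning offset in >= 90% of seeds", {
  hits <- 0L
  n_seed <- 20L
  for (s in seq_len(n_seed)) {
    set.seed(1000 + s)
    d <- purrr::map_dfr(
      c("pre_spawning_lower", "pre_spawning_upper",
        "spawning_early", "spawning_late"),
      function(g) {
        l <- runif(25, 400, 520)
        off <- if (startsWith(g, "spawning")) -0.1 else 0
        tibble::tibble(
          fork_length_mm = l,
          paf = 10^(-2.5 + 3 * log10(l) + off + rnorm(25, 0, 0.105)),
          group = g
        )
      })
    ctr <- tidy(decline_ancova(d))
    pooled <- ctr[ctr$contrast == "spawning - pre_spawning", ]
    if (pooled$estimate < 0 && pooled$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_seed, 0.9)
})

test_that("interaction-free data keep the interaction term quiet", {
  # type-I behaviour: over seeds, interaction p-values spread over (0,1)
  # rather than piling below alpha
  ps <- purrr::map_dbl(seq_len(24), function(s) {
    set.seed(2000 + s)
    d <- purrr::map_dfr(c("pre_a", "pre_b"), function(g) {
      l <- runif(20, 400, 520)
      tibble::tibble(fork_length_mm = l,
                     paf = 10^(-2.5 + 3 * log10(l) + rnorm(20, 0, 0.1)),
                     group = g)
    })
    decline_ancova(d, pre_groups = "pre_a")$interaction_p
  })
  expect_lte(mean(ps < 0.05), 0.25)
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.75)
})

test_that("degenerate ANCOVA designs fail informatively", {
  d <- tibble::tibble(fork_length_mm = rep(450, 6),
                      paf = c(1, 2, 3, 4, 5, 6) * 1e5,
                      group = rep(c("pre_a", "spawn_b"), each = 3))
  expect_error(decline_ancova(d), class = "fecundr_domain_error")
  expect_error(decline_ancova(make_fish(3)[0, ] |>
                                dplyr::mutate(paf = numeric(),
                                              group = character())),
               class = "fecundr_domain_error")
})
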