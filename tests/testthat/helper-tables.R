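# In-code fixtures shared across test files.

make_fish <- function(n = 3) {
  tibble::tibble(
    fish_id = sprintf("f%02d", seq_len(n)),
    date = as.Date("2015-05-12") + seq_len(n),
    site = "H",
    fork_length_mm = seq(420, length.out = n, by = 10),
    total_mass_g = seq(1400, length.out = n, by = 50),
    ovary_mass_g = seq(250, length.out = n, by = 10),
    age_yr = rep(5L, n),
    macro_class = rep("A", n),
    maos = rep("NM1", n),
    pof_age = rep("none", n)
  )
}

make_subsample <- function(fish_id = "f01", mass = 0.3, t = 0, s = 300,
                           p = 500, m = 0) {
  tibble::tibble(
    fish_id = fish_id, subsample_mass_g = mass,
    count_primary = p, count_transitional = t,
    count_secondary = s, count_maturation = m
  )
}

# closed-form simple linear regression, the independent OLS oracle
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  b <- sxy / sxx
  a <- mean(y) - b * mean(x)
  r <- sxy / sqrt(sxx * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  list(slope = b, intercept = a, r = r, p_value = p)
}

# independent ML fit of a zero-truncated normal: direct likelihood
# optimization over a (mu, log sigma) grid refined by nlminb
trunc_norm_mle_oracle <- function(x, lb = 0) {
  nll <- function(p) {
    mu <- p[1]; s <- exp(p[2])
    -sum(stats::dnorm(x, mu, s, log = TRUE)) +
      length(x) * stats::pnorm(lb, mu, s, lower.tail = FALSE, log.p = TRUE)
  }
  best <- NULL
  for (mu0 in stats::quantile(x, c(0.3, 0.5, 0.7), names = FALSE)) {
    for (ls0 in log(stats::sd(x) * c(0.5, 1, 2))) {
      fit <- stats::nlminb(c(mu0, ls0), nll,
                           control = list(rel.tol = 1e-14))
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
  }
  c(mean = best$par[1], sd = exp(best$par[2]))
}
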