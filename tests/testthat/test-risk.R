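test_that("Weibull contact-time quantiles and draws follow the stated law", {
  d <- contact_time_distribution(scale = 1, shape = 3)
  expect_equal(quantile_contact_time(d, 0.5), log(2)^(1 / 3))
  expect_equal(quantile_contact_time(d, 0.5), 0.8850, tolerance = 1e-4)
  ## determinism under a fixed seed, and restoration of the RNG state
  x1 <- sample_contact_times(d, 100, seed = 5)
  x2 <- sample_contact_times(d, 100, seed = 5)
  expect_identical(x1, x2)
  ## empirical CDF vs analytic CDF (Kolmogorov-Smirnov distance)
  x <- sample_contact_times(d, 1e5, seed = 9)
  ks <- max(abs(ecdf(x)(sort(x)) - cdf_contact_time(d, sort(x))))
  expect_lt(ks, 0.01)
  ## degenerate distribution
  dd <- contact_time_distribution(scale = 7, shape = Inf)
  expect_equal(quantile_contact_time(dd, c(0.1, 0.9)), c(7, 7))
  expect_error(contact_time_distribution(-1, 3))
})

test_that("exceedance probabilities invert the monotone loading map", {
  sc <- fixture("T1_caprolactam", air_gap = 1e-2)
  d <- contact_time_distribution(scale = 7 * 86400, shape = 3)
  map <- loading_map(sc, receiving = c("1", "2", "3"), t_scale = d$scale)
  expect_true(all(diff(map$m) >= 0))
  expect_equal(exceedance_probability(0, map, d), 1)
  expect_equal(exceedance_probability(2 * map$m_max, map, d), 0)
  ## non-increasing in m, range [0, 1]
  mg <- seq(0, map$m_max, length.out = 30)
  p <- exceedance_probability(mg, map, d)
  expect_true(all(diff(p) <= 1e-12))
  expect_true(all(p >= 0 & p <= 1))
  ## Monte-Carlo oracle within 3 standard errors at fixed thresholds
  draws <- sample_contact_times(d, 1e5, seed = 123)
  mdraws <- map$Omega(pmin(draws, max(map$t)))
  for (q in c(0.25, 0.5, 0.75)) {
    m <- map$Omega(quantile_contact_time(d, q))
    phat <- mean(mdraws >= m)
    se <- sqrt(phat * (1 - phat) / 1e5)
    expect_lt(abs(exceedance_probability(m, map, d) - phat), 3 * se + 1e-4)
  }
})

test_that("percentile kinetics are monotone in the percentile and reduce to the deterministic run", {
  sc <- loading_migration_scenario("T1", "caprolactam", air_gap = 1e-2,
                                   t1 = 7 * 86400, t2 = 30 * 86400)
  d <- contact_time_distribution(scale = 7 * 86400, shape = 3)
  tt <- exp(seq(log(3600), log(30 * 86400), length.out = 20))
  f <- sapply(c(0.5, 0.95), function(q) {
    sol <- percentile_kinetics(sc, d, q, times = tt)
    approx(sol$kinetics$times, sol$kinetics$amounts[, "F"], xout = tt)$y
  })
  expect_true(all(f[, 2] >= f[, 1] - 1e-12))
  ## point mass at the scale reproduces the deterministic two-step scenario
  det <- contact_time_distribution(scale = 7 * 86400, shape = Inf)
  sol_d <- percentile_kinetics(sc, det, 0.5, times = tt)
  ref <- run_scenario(sc, times = list(NULL, tt))
  expect_equal(sol_d$kinetics$amounts, ref$steps[[2]]$kinetics$amounts)
  expect_equal(attr(sol_d, "t1"), 7 * 86400)
  ## large shape concentrates the percentile curves on each other
  dn <- contact_time_distribution(scale = 7 * 86400, shape = 80)
  fn <- sapply(c(0.5, 0.95), function(q) {
    sol <- percentile_kinetics(sc, dn, q, times = tt)
    approx(sol$kinetics$times, sol$kinetics$amounts[, "F"], xout = tt)$y
  })
  spread_wide <- max(f[, 2] - f[, 1])
  spread_narrow <- max(fn[, 2] - fn[, 1])
  expect_lt(spread_narrow, 0.1 * spread_wide)
})

test_that("in the square-root loading regime a factor two covers four times the contact time", {
  ## perfect contact: the early bag uptake is diffusion controlled
  sc <- fixture("T1_caprolactam", air_gap = 0)
  map <- loading_map(sc, receiving = c("1", "2", "3"), t_scale = 400,
                     grid = grid_spec(nodes = 300, min_nodes = 24))
  expect_equal(map$Omega(4 * 400) / map$Omega(400), 2, tolerance = 0.05)
})

test_that("risk reports tabulate percentile and deterministic curves together", {
  sc <- loading_migration_scenario("T1", "caprolactam", air_gap = 1e-2,
                                   t1 = 7 * 86400, t2 = 10 * 86400)
  d <- contact_time_distribution(scale = 7 * 86400, shape = 3)
  tt <- exp(seq(log(86400), log(10 * 86400), length.out = 8))
  rep <- risk_report(sc, d, percentiles = c(0.5, 0.95), times = tt)
  expect_named(rep, c("time", "q50", "q95", "deterministic"))
  expect_true(all(rep$q95 >= rep$q50 - 1e-12))
})
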