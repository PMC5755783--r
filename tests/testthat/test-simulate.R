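# Trial simulators and censoring mechanisms.

test_that("censoring-time mechanisms have the stated distributions", {
  set.seed(11)
  u <- draw_censoring_times(window_3yr(), 1e5)
  expect_gte(min(u), 2.5)
  expect_lte(max(u), 3.5)
  expect_lt(abs(mean(u) - 3.0), 4 * sd(u) / sqrt(1e5))

  expect_identical(draw_censoring_times(censoring_spec("none"), 5),
                   rep(Inf, 5))

  mix <- censoring_spec("dropout_mixture", window_lo = 2.5, window_hi = 3.5,
                        dropout_prob = 0.2, dropout_hi = 2.5)
  u <- draw_censoring_times(mix, 1e5)
  frac_early <- mean(u < 2.5)
  expect_lt(abs(frac_early - 0.2), 4 * sqrt(0.2 * 0.8 / 1e5))

  nw <- censoring_spec("normal_window", mean = 36, sd = 2.4)
  u <- draw_censoring_times(nw, 1e5)
  expect_true(all(u > 0))
  expect_lt(abs(mean(u) - 36), 4 * 2.4 / sqrt(1e5))
})

test_that("censoring specs validate their fields", {
  expect_error(censoring_spec("uniform_window", window_lo = 3, window_hi = 2),
               "window_lo")
  expect_error(censoring_spec("dropout_mixture", window_lo = 2.5,
                              window_hi = 3.5, dropout_prob = 1.4,
                              dropout_hi = 2.5), "dropout_prob")
  expect_error(censoring_spec("normal_window", mean = 36, sd = 0), "sd")
  expect_error(censoring_spec("made_up"))
})

test_that("Weibull-gamma simulator recovers the closed-form moments", {
  set.seed(22)
  d <- simulate_trial(table_wg(), n_per_arm = 1e5)
  expect_true(all(d$event == 1L))
  expect_true(all(d$time > 0) && all(d$cost > 0))
  t1 <- d$time[d$arm == 1]; t0 <- d$time[d$arm == 0]
  expect_lt(abs(mean(t1) - 3.0), 4 * sd(t1) / sqrt(length(t1)))
  expect_lt(abs(mean(t0) - 1.0715754), 4 * sd(t0) / sqrt(length(t0)))
  # law of total expectation: E[C] = beta + gamma * E[T]
  c1 <- d$cost[d$arm == 1]; c0 <- d$cost[d$arm == 0]
  expect_lt(abs(mean(c1) - (100 + 60 * 3)), 4 * sd(c1) / sqrt(length(c1)))
  expect_lt(abs(mean(c0) - (50 + 75 * 1.0715754)),
            4 * sd(c0) / sqrt(length(c0)))
})

test_that("Weibull-gamma censoring proportion matches the quadrature oracle", {
  # Pr(T > U) for U ~ Uniform(2.5, 3.5): average of the Weibull survival
  oracle0 <- integrate(function(u) exp(-(u / 0.9)^0.75), 2.5, 3.5)$value
  oracle1 <- integrate(function(u) exp(-sqrt(u / 1.5)), 2.5, 3.5)$value
  set.seed(23)
  d <- simulate_trial(table_wg(), n_per_arm = 4e4, spec = window_3yr())
  for (k in 0:1) {
    frac <- mean(d$event[d$arm == k] == 0)
    oracle <- if (k == 0) oracle0 else oracle1
    expect_lt(abs(frac - oracle), 4 * sqrt(oracle * (1 - oracle) / 4e4))
  }
  # observed censored times never exceed the window end
  expect_lte(max(d$time[d$event == 0]), 3.5)
  # censored records behave as min(T, U): all observed times <= window end
  expect_true(all(d$time[d$event == 0] >= 2.5))
})

test_that("normal-normal simulator matches its marginal summaries", {
  set.seed(24)
  d <- simulate_trial(table_nn(), n_per_arm = 1e5)
  expect_true(all(d$time > 0) && all(d$cost > 0))
  for (k in 0:1) {
    s <- nn_marginal_summary(table_nn(), k)
    t <- d$time[d$arm == k]; cc <- d$cost[d$arm == k]
    n <- length(t)
    expect_lt(abs(mean(t) - s["mean_t"]), 4 * s["sd_t"] / sqrt(n) + 0.02)
    expect_lt(abs(mean(cc) - s["mean_c"]), 4 * s["sd_c"] / sqrt(n) + 0.05)
    expect_lt(abs(sd(cc) - s["sd_c"]), 0.02 * s["sd_c"])
    expect_lt(abs(cor(t, cc) - s["corr"]), 0.02)
  }
})

test_that("normal-normal censoring proportion matches the Gaussian oracle", {
  # P(T > U) with T ~ N(mu, tauT^2), U ~ N(36, 2.4^2) independent,
  # corrected for the (tiny) positivity truncation of T
  p <- table_nn()
  set.seed(25)
  d <- simulate_trial(p, n_per_arm = 5e4,
                      spec = censoring_spec("normal_window",
                                            mean = 36, sd = 2.4))
  for (k in 0:1) {
    mu <- if (k == 0) p$mu0 else p$mu1
    tau <- sqrt(if (k == 0) p$tauT0sq else p$tauT1sq)
    oracle <- pnorm((mu - 36) / sqrt(tau^2 + 2.4^2)) / pnorm(mu / tau)
    frac <- mean(d$event[d$arm == k] == 0)
    expect_lt(abs(frac - oracle),
              4 * sqrt(oracle * (1 - oracle) / 5e4) + 0.003)
  }
})

test_that("simulation is deterministic under a fixed seed", {
  set.seed(77); d1 <- simulate_trial(table_wg(), 500, window_3yr())
  set.seed(77); d2 <- simulate_trial(table_wg(), 500, window_3yr())
  expect_identical(d1, d2)
  set.seed(77); d3 <- simulate_trial(table_nn(), 200)
  set.seed(77); d4 <- simulate_trial(table_nn(), 200)
  expect_identical(d3, d4)
})

test_that("scaled censored-cost convention stays below the latent total", {
  # under the scaled convention the recorded censored cost is U/T of the
  # latent total, so its mean is below the accrued-at-U mean
  set.seed(31)
  heavy <- censoring_spec("uniform_window", window_lo = 0.5, window_hi = 1)
  d_acc <- simulate_trial(table_wg(), 2e4, heavy, censored_cost = "accrued")
  set.seed(31)
  d_sc <- simulate_trial(table_wg(), 2e4, heavy, censored_cost = "scaled")
  expect_lt(mean(d_sc$cost[d_sc$event == 0]),
            mean(d_acc$cost[d_acc$event == 0]))
  expect_true(all(d_sc$cost > 0))
})

test_that("trial data round-trips through the CSV interchange format", {
  set.seed(5)
  d <- simulate_trial(table_wg(), 50, window_3yr())
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial(d, path)
  header <- readLines(path, n = 1)
  expect_identical(header, "time,cost,arm,event")
  d2 <- read_trial(path)
  expect_equal(as.data.frame(d2), as.data.frame(d), tolerance = 1e-12)
  # malformed input is rejected with a named-column message
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("time,cost\n1,2", bad)
  expect_error(read_trial(bad), "arm")
})

test_that("trial_data enforces its invariants", {
  expect_error(trial_data(c(1, -1), c(1, 1), c(0, 1), c(1, 1)), "positive")
  expect_error(trial_data(1, 1, 2, 1), "arm")
  expect_error(trial_data(1, 1, 0, 2), "event")
  expect_error(trial_data(c(1, 2), 1, c(0, 1), c(1, 1)), "length")
})
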