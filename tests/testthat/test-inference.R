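# The data-augmentation sampler: imputation, fitting, and the posterior
# INMB decision quantity.

test_that("imputation respects the truncation contract", {
  set.seed(41)
  for (params in list(table_wg(), table_nn())) {
    tm <- if (inherits(params, "wg_params")) 2.5 else 36
    cst <- if (inherits(params, "wg_params")) 150 else 600
    imp <- impute_censored(tm, cst, arm = 1, params = params, n = 500)
    expect_true(all(imp$latent_t > tm))
    expect_true(all(imp$latent_c > cst))
  }
})

test_that("with a negligible cost tilt the latent time is truncated-Weibull", {
  # c -> 0 makes S_C|T(c|t) ~ 1, so latent times follow the Weibull
  # truncated to (t_i, Inf); compare to the inverse-CDF oracle by KS
  set.seed(42)
  p <- table_wg()
  t_cens <- 2.5
  imp <- impute_censored(t_cens, 1e-8, arm = 1, params = p, n = 2e4)
  oracle_cdf <- function(q) {
    s0 <- pweibull(t_cens, 0.5, 1.5, lower.tail = FALSE)
    (pweibull(pmax(q, t_cens), 0.5, 1.5) - (1 - s0)) / s0
  }
  ks <- suppressWarnings(ks.test(imp$latent_t, oracle_cdf))
  expect_gt(ks$p.value, 1e-3)
})

test_that("fitting is deterministic under a fixed seed", {
  set.seed(7)
  d <- simulate_trial(table_wg(), 40, window_3yr())
  f1 <- suppressWarnings(fit_trial(d, wg_analysis_prior(),
                                   quick_mcmc(burn_in = 100, keep = 200,
                                              seed = 99)))
  f2 <- suppressWarnings(fit_trial(d, wg_analysis_prior(),
                                   quick_mcmc(burn_in = 100, keep = 200,
                                              seed = 99)))
  expect_identical(f1$draws, f2$draws)
})

test_that("uncensored data bypass augmentation entirely", {
  set.seed(9)
  d <- simulate_trial(table_nn(), 60)
  f <- suppressWarnings(fit_trial(d, nn_analysis_prior(),
                                  quick_mcmc(keep = 300, seed = 3)))
  expect_false(f$augmented)
  expect_identical(f$n_censored, 0L)
})

test_that("degenerate datasets are rejected", {
  set.seed(10)
  d <- simulate_trial(table_wg(), 20)
  one_arm <- trial_data(d$time[d$arm == 0], d$cost[d$arm == 0],
                        d$arm[d$arm == 0], d$event[d$arm == 0])
  expect_error(fit_trial(one_arm, wg_analysis_prior(), quick_mcmc()),
               "arm")
  all_cens <- trial_data(d$time, d$cost, d$arm,
                         ifelse(d$arm == 1, 0L, 1L))
  expect_error(fit_trial(all_cens, wg_analysis_prior(), quick_mcmc()),
               "censored")
})

test_that("retained draws respect the positivity constraints", {
  set.seed(12)
  d <- simulate_trial(table_wg(), 60, window_3yr())
  f <- suppressWarnings(fit_trial(d, wg_analysis_prior(),
                                  quick_mcmc(keep = 400, seed = 5)))
  expect_true(all(f$draws > 0))
  expect_setequal(colnames(f$draws), names(unclass(table_wg())))
  d2 <- simulate_trial(table_nn(), 60)
  f2 <- suppressWarnings(fit_trial(d2, nn_analysis_prior(),
                                   quick_mcmc(keep = 400, seed = 5)))
  vv <- c("tauT0sq", "tauT1sq", "tauC0sq", "tauC1sq")
  expect_true(all(f2$draws[, vv] > 0))
})

test_that("complete-data fits recover the generating parameters", {
  set.seed(13)
  d <- simulate_trial(table_wg(), 2000)
  f <- suppressWarnings(fit_trial(d, wg_analysis_prior(),
                                  quick_mcmc(burn_in = 400, keep = 800,
                                             seed = 21)))
  s <- summary(f)
  truth <- unlist(unclass(table_wg()))[rownames(s)]
  z <- abs(s$mean - truth) / s$sd
  expect_true(all(z < 3), info = paste(rownames(s), round(z, 2),
                                       collapse = "; "))
})

test_that("normal-normal fits recover the effectiveness difference under censoring", {
  # the fixture's own study-end mechanism (~24% censoring)
  set.seed(14)
  d <- simulate_trial(table_nn(), 2000,
                      censoring_spec("normal_window", mean = 36, sd = 2.4))
  expect_gt(mean(d$event == 0), 0.2)
  f <- suppressWarnings(fit_trial(d, nn_analysis_prior(),
                                  quick_mcmc(burn_in = 400, keep = 1000,
                                             seed = 22)))
  diff_draws <- f$draws[, "mu1"] - f$draws[, "mu0"]
  expect_lt(abs(mean(diff_draws) - 8.5), 3 * sd(diff_draws))
})

test_that("posterior INMB follows the affine map of the draws", {
  # hand-built posterior concentrated at the design values
  n_draws <- 200
  draws <- matrix(rep(unlist(unclass(table_wg())), each = n_draws),
                  nrow = n_draws,
                  dimnames = list(NULL, names(unclass(table_wg()))))
  fake <- structure(list(draws = draws, model = "wg"), class = "ce_fit")
  out <- posterior_inmb(fake, wtp = 250)
  m0 <- 0.9 * gamma(1 + 1 / 0.75); m1 <- 1.5 * gamma(3)
  expected <- (m1 - m0) * 250 - ((100 + 60 * m1) - (50 + 75 * m0))
  expect_equal(unique(out$inmb_draws), expected, tolerance = 1e-12)
  expect_equal(out$prob_positive, 1)
  # identical arms: INMB is exactly zero, and strict ">" counts it a failure
  eq <- unclass(table_wg())
  eq[6:10] <- eq[1:5]
  draws_eq <- matrix(rep(unlist(eq), each = n_draws), nrow = n_draws,
                     dimnames = list(NULL, names(eq)))
  fake_eq <- structure(list(draws = draws_eq, model = "wg"),
                       class = "ce_fit")
  expect_equal(posterior_inmb(fake_eq, wtp = 100)$prob_positive, 0)
})

test_that("Pr(INMB > 0) is nondecreasing in WTP when all effect draws are positive", {
  set.seed(15)
  n_draws <- 500
  draws <- cbind(alpha0 = runif(n_draws, 0.7, 0.8),
                 lambda0 = runif(n_draws, 0.85, 0.95),
                 nu0 = rep(1.2, n_draws), beta0 = runif(n_draws, 45, 55),
                 gamma0 = runif(n_draws, 70, 80),
                 alpha1 = runif(n_draws, 0.45, 0.55),
                 lambda1 = runif(n_draws, 1.4, 1.6),
                 nu1 = rep(3, n_draws), beta1 = runif(n_draws, 95, 105),
                 gamma1 = runif(n_draws, 55, 65))
  fake <- structure(list(draws = draws, model = "wg"), class = "ce_fit")
  pr <- prob_ce(fake, seq(0, 350, by = 25))
  expect_true(all(diff(pr) >= 0))
})

test_that("MCMC posterior agrees with an independent lattice quadrature posterior", {
  # Small censored dataset; every parameter except the two Weibull scales
  # held at truth. The oracle integrates prior x censored likelihood
  # (loglik_record quadrature) over a 2-D log-spaced lattice; the sampler
  # route uses data augmentation and never touches that integral.
  set.seed(16)
  d <- simulate_trial(table_wg(), 3,
                      censoring_spec("uniform_window", window_lo = 1.5,
                                     window_hi = 2.5))
  truth <- unclass(table_wg())
  fixlist <- truth[setdiff(names(truth), c("lambda0", "lambda1"))]

  grid_post <- function(arm, lam_name) {
    grid <- exp(seq(log(0.05), log(40), length.out = 220))
    rows <- which(d$arm == arm)
    lp <- vapply(grid, function(l) {
      p <- do.call(wg_params, modifyList(truth, setNames(list(l), lam_name)))
      sum(vapply(rows, function(i)
        loglik_record(d$time[i], d$cost[i], d$arm[i], d$event[i], p),
        numeric(1))) + dgamma(l, 0.1, 0.1, log = TRUE) + log(l)
    }, numeric(1))
    w <- exp(lp - max(lp)); w / sum(w)
  }
  g <- exp(seq(log(0.05), log(40), length.out = 220))
  w0 <- grid_post(0, "lambda0"); w1 <- grid_post(1, "lambda1")
  # Pr(INMB > 0 | wtp): separable weights, exact over the lattice
  m0 <- g * gamma(1 + 1 / truth$alpha0); m1 <- g * gamma(1 + 1 / truth$alpha1)
  wtp <- 150
  inmb_grid <- outer(m1, m0, function(a, b)
    (a - b) * wtp - (truth$beta1 + truth$gamma1 * a -
                     truth$beta0 - truth$gamma0 * b))
  pr_oracle <- sum(outer(w1, w0) * (inmb_grid > 0))

  f <- suppressWarnings(fit_trial(d, wg_analysis_prior(),
                                  mcmc_settings(chains = 1, burn_in = 1500,
                                                keep = 12000, seed = 33),
                                  fix = fixlist))
  pr_mcmc <- unname(prob_ce(f, wtp))
  expect_lt(abs(pr_mcmc - pr_oracle), 0.02)
})

test_that("posterior draws and summary round-trip to CSV", {
  set.seed(17)
  d <- simulate_trial(table_nn(), 50)
  f <- suppressWarnings(fit_trial(d, nn_analysis_prior(),
                                  quick_mcmc(chains = 2, keep = 200,
                                             seed = 6)))
  dir <- withr::local_tempdir()
  write_fit(f, dir)
  draws <- read.csv(file.path(dir, "draws.csv"), check.names = FALSE)
  expect_identical(nrow(draws), nrow(f$draws))
  expect_true(all(c("chain", "iter", "mu0", "tauC1sq") %in% names(draws)))
  s <- read.csv(file.path(dir, "summary.csv"))
  expect_identical(nrow(s), 10L)
  expect_true(all(c("mean", "sd", "rhat", "ess") %in% names(s)))
})
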