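# Closed-form quantities of the two joint models.

test_that("weibull_mean matches the quadrature of the survival function", {
  # frozen from integrate(exp(-(t/lambda)^alpha), 0, Inf)
  expect_equal(weibull_mean(0.5, 1.5), 3.0, tolerance = 1e-12)
  expect_equal(weibull_mean(1.0, 2.0), 2.0, tolerance = 1e-12)  # exponential
  expect_equal(weibull_mean(0.75, 0.9), 1.0715754139, tolerance = 1e-9)
  # recomputed oracle for a fresh parameter set
  oracle <- integrate(function(t) exp(-(t / 1.3)^1.7), 0, Inf,
                      rel.tol = 1e-12)$value
  expect_equal(weibull_mean(1.7, 1.3), oracle, tolerance = 1e-9)
})

test_that("weibull_mean rejects non-positive arguments", {
  expect_error(weibull_mean(0, 1), "positive")
  expect_error(weibull_mean(1, -2), "positive")
  expect_error(weibull_mean(NA_real_, 1), "positive")
})

test_that("Weibull-gamma expected INMB reproduces the fixture line 1.93*WTP - 150", {
  p <- table_wg()
  comp <- inmb_components(p)
  expect_equal(round(comp$d_effect, 2), 1.93)
  expect_equal(round(comp$d_cost, -1), 150)
  expect_equal(inmb(p, 100), 1.928425 * 100 - 149.631844, tolerance = 1e-5)
  # root of the affine form
  expect_equal(inmb(p, comp$d_cost / comp$d_effect), 0, tolerance = 1e-10)
  # affine and increasing in wtp with slope equal to the mean difference
  w <- c(0, 50, 125, 300)
  expect_equal(diff(inmb(p, w)) / diff(w), rep(comp$d_effect, 3))
})

test_that("identical arms give identically zero INMB", {
  p <- wg_params(alpha0 = 0.8, lambda0 = 1.1, nu0 = 2, beta0 = 40, gamma0 = 30,
                 alpha1 = 0.8, lambda1 = 1.1, nu1 = 2, beta1 = 40, gamma1 = 30)
  expect_equal(inmb(p, c(0, 100, 1e4)), c(0, 0, 0))
  q <- nn_params(mu0 = 20, tauT0sq = 4, theta1 = 10, theta2 = 2, tauC0sq = 9,
                 mu1 = 20, tauT1sq = 4, theta3 = 10, theta4 = 2, tauC1sq = 9)
  expect_equal(inmb(q, c(0, 77)), c(0, 0))
})

test_that("normal-normal expected INMB reproduces the fixture line 8.5*WTP - 570", {
  p <- table_nn()
  comp <- inmb_components(p)
  expect_equal(comp$d_effect, 8.5)
  expect_equal(round(comp$d_cost), 570)
  expect_equal(inmb(p, 100), 279.97, tolerance = 1e-10)
  expect_equal(inmb(p, 0), -570.03, tolerance = 1e-10)
})

test_that("conditional cost density is a proper density with the stated moments", {
  p <- table_wg()
  for (case in list(list(t = 1, arm = 0L), list(t = 2.7, arm = 1L))) {
    a <- if (case$arm == 0L) c(50, 75, 1.2) else c(100, 60, 3)
    mu <- a[1] + a[2] * case$t
    total <- integrate(wg_cost_density, 0, Inf, t = case$t, arm = case$arm,
                       params = p, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-6)
    m1 <- integrate(function(c) c * wg_cost_density(c, case$t, case$arm, p),
                    0, Inf, rel.tol = 1e-10)$value
    expect_equal(m1, mu, tolerance = 1e-6)
    m2 <- integrate(function(c) c^2 * wg_cost_density(c, case$t, case$arm, p),
                    0, Inf, rel.tol = 1e-10)$value
    expect_equal(m2 - m1^2, mu^2 / a[3], tolerance = 1e-5)
  }
})

test_that("sampling from the cost law matches its analytic mean", {
  p <- table_wg()
  set.seed(101)
  draws <- rgamma(1e6, shape = p$nu0, rate = p$nu0 / (p$beta0 + p$gamma0 * 1))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 125), 4 * se)
})

test_that("wg_cost_density rejects non-positive cost or time", {
  expect_error(wg_cost_density(-1, 1, 0, table_wg()), "positive")
  expect_error(wg_cost_density(1, 0, 0, table_wg()), "positive")
})

test_that("marginal bivariate summary reproduces the fixture displays", {
  p <- table_nn()
  s1 <- nn_marginal_summary(p, arm = 1)
  expect_equal(round(unname(s1["mean_c"])), 700)
  expect_equal(round(unname(s1["sd_c"]), 1), 101.5)
  expect_equal(round(unname(s1["corr"]), 1), 0.4)
  s0 <- nn_marginal_summary(p, arm = 0)
  expect_equal(round(unname(s0["mean_c"])), 130)
  expect_equal(round(unname(s0["sd_c"])), 30)
  expect_equal(round(unname(s0["corr"]), 1), 0.3)
})

test_that("marginal summary round-trips to the conditional slope", {
  p <- table_nn()
  for (arm in 0:1) {
    s <- nn_marginal_summary(p, arm)
    slope <- unname(s["corr"] * s["sd_c"] / s["sd_t"])
    expect_equal(slope, if (arm == 0) p$theta2 else p$theta4,
                 tolerance = 1e-10)
  }
  # zero slope means independence
  q <- nn_params(mu0 = 20, tauT0sq = 4, theta1 = 10, theta2 = 0, tauC0sq = 9,
                 mu1 = 21, tauT1sq = 4, theta3 = 10, theta4 = 1, tauC1sq = 9)
  expect_equal(unname(nn_marginal_summary(q, 0)["corr"]), 0)
})

test_that("parameter containers validate their invariants", {
  expect_error(wg_params(alpha0 = -1, lambda0 = 0.9, nu0 = 1.2, beta0 = 50,
                         gamma0 = 75, alpha1 = 0.5, lambda1 = 1.5, nu1 = 3,
                         beta1 = 100, gamma1 = 60), "positive")
  expect_error(nn_params(mu0 = 25, tauT0sq = 0, theta1 = 1, theta2 = 1,
                         tauC0sq = 1, mu1 = 33, tauT1sq = 1, theta3 = 1,
                         theta4 = 1, tauC1sq = 1), "positive")
  # negative means/coefficients are legitimate for the normal model
  expect_s3_class(nn_params(mu0 = -1, tauT0sq = 1, theta1 = -5, theta2 = 0,
                            tauC0sq = 1, mu1 = 2, tauT1sq = 1, theta3 = 0,
                            theta4 = -1, tauC1sq = 1), "nn_params")
})
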