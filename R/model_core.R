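#' Mean of a Weibull distribution
#'
#' Expected value \eqn{\lambda \Gamma(1 + 1/\alpha)} of a Weibull
#' distribution with shape `alpha` and scale `lambda` (the survival
#' parameterization in which \eqn{S(t) = \exp[-(t/\lambda)^\alpha]}).
#'
#' @param alpha shape, strictly positive.
#' @param lambda scale, strictly positive.
#' @return The mean survival time; vectorized over both arguments.
#' @examples
#' weibull_mean(1, 2)     # exponential with mean 2
#' weibull_mean(0.5, 1.5) # heavy-tailed: mean 3
#' @export
weibull_mean <- function(alpha, lambda) {
  if (any(!is.finite(alpha)) || any(!is.finite(lambda)) ||
      any(alpha <= 0) || any(lambda <= 0))
    stop("weibull_mean: 'alpha' and 'lambda' must be strictly positive",
         call. = FALSE)
  lambda * gamma(1 + 1 / alpha)
}

#' Expected incremental net monetary benefit
#'
#' The incremental net monetary benefit (INMB) at willingness-to-pay `wtp`
#' implied by a parameter set:
#' \deqn{INMB(WTP) = [E(T|Z=1) - E(T|Z=0)] \times WTP -
#'   [E(C|Z=1) - E(C|Z=0)].}
#' For the Weibull-gamma model the arm means are
#' \eqn{m_k = \lambda_k \Gamma(1 + 1/\alpha_k)} and expected cost
#' \eqn{\beta_k + \gamma_k m_k}; for the normal-normal model they are
#' \eqn{\mu_k} and \eqn{\theta_{int,k} + \theta_{slope,k}\mu_k}. The value
#' is affine in `wtp` with slope equal to the effectiveness difference.
#'
#' @param params a [wg_params()] or [nn_params()] object.
#' @param wtp willingness to pay per unit of survival time (cost units per
#'   time unit); may be a vector.
#' @return Numeric vector of INMB values, one per `wtp`.
#' @examples
#' inmb(wg_design_values(), wtp = c(100, 250))
#' inmb(nn_design_values(), wtp = 100)
#' @export
inmb <- function(params, wtp) UseMethod("inmb")

#' @export
inmb.wg_params <- function(params, wtp) {
  stopifnot(is.numeric(wtp), all(wtp >= 0))
  eff <- inmb_components(params)
  eff$d_effect * wtp - eff$d_cost
}

#' @export
inmb.nn_params <- function(params, wtp) {
  stopifnot(is.numeric(wtp), all(wtp >= 0))
  eff <- inmb_components(params)
  eff$d_effect * wtp - eff$d_cost
}

#' Effectiveness and cost differences entering the INMB
#'
#' Returns the two building blocks of the expected INMB: the incremental
#' effectiveness `d_effect` (mean survival, treatment minus control — the
#' coefficient on WTP) and the incremental expected cost `d_cost` (the
#' intercept subtracted from the INMB line).
#'
#' @param params a [wg_params()] or [nn_params()] object.
#' @return A list with elements `d_effect` and `d_cost`.
#' @examples
#' inmb_components(wg_design_values()) # approx 1.93 and 150
#' @export
inmb_components <- function(params) UseMethod("inmb_components")

#' @export
inmb_components.wg_params <- function(params) {
  m0 <- weibull_mean(params$alpha0, params$lambda0)
  m1 <- weibull_mean(params$alpha1, params$lambda1)
  # per-arm expected costs first, so identical arms cancel exactly
  list(d_effect = m1 - m0,
       d_cost = (params$beta1 + params$gamma1 * m1) -
                (params$beta0 + params$gamma0 * m0))
}

#' @export
inmb_components.nn_params <- function(params) {
  list(d_effect = params$mu1 - params$mu0,
       d_cost = (params$theta3 + params$theta4 * params$mu1) -
                (params$theta1 + params$theta2 * params$mu0))
}

#' Conditional cost density of the Weibull-gamma model
#'
#' Density of accrued cost c given survival time t in arm `arm`: gamma with
#' shape \eqn{\nu_k} reparameterized to have mean
#' \eqn{\mu_k(t) = \beta_k + \gamma_k t}, i.e.
#' \deqn{f_{C|T}(c|t) = (\nu/\mu(t))^\nu c^{\nu-1}
#'   \exp[-(\nu/\mu(t)) c] / \Gamma(\nu).}
#' The conditional variance is \eqn{\mu(t)^2/\nu}.
#'
#' @param c cost, strictly positive; vectorized.
#' @param t survival time, strictly positive scalar.
#' @param arm 0 or 1.
#' @param params a [wg_params()] object.
#' @param log return the log density?
#' @return Density values.
#' @export
wg_cost_density <- function(c, t, arm, params, log = FALSE) {
  if (any(c <= 0) || any(t <= 0))
    stop("wg_cost_density: 'c' and 't' must be strictly positive",
         call. = FALSE)
  arm <- check_arm(arm)
  a <- wg_arm(params, arm)
  mu <- a$beta + a$gamma * t
  dgamma(c, shape = a$nu, rate = a$nu / mu, log = log)
}

#' Marginal bivariate summary of the normal-normal model
#'
#' Converts the conditional cost parameterization (intercept, slope on time,
#' conditional variance) of one arm into the marginal bivariate-normal
#' display: marginal cost mean `intercept + slope * mu`, marginal cost sd
#' \eqn{\sqrt{slope^2 \tau^2_T + \tau^2_C}}, and time-cost correlation
#' \eqn{slope\, \tau_T / sd_C}.
#'
#' @param params an [nn_params()] object.
#' @param arm 0 or 1.
#' @return Named numeric vector `(mean_t, mean_c, sd_t, sd_c, corr)`.
#' @examples
#' nn_marginal_summary(nn_design_values(), arm = 1)
#' @export
nn_marginal_summary <- function(params, arm) {
  arm <- check_arm(arm)
  a <- nn_arm(params, arm)
  sd_t <- sqrt(a$tauTsq)
  sd_c <- sqrt(a$b^2 * a$tauTsq + a$tauCsq)
  c(mean_t = a$mu, mean_c = a$a + a$b * a$mu,
    sd_t = sd_t, sd_c = sd_c, corr = a$b * sd_t / sd_c)
}
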