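#' Weibull-gamma model parameters
#'
#' Container for the ten parameters of the Weibull-gamma joint
#' cost-effectiveness model. Survival time in arm k (0 = control,
#' 1 = treatment) is Weibull with shape `alpha_k` and scale `lambda_k`,
#' using the parameterization
#' \deqn{f_T(t) = \alpha (t/\lambda)^{\alpha-1}
#'   \exp[-(t/\lambda)^\alpha] / \lambda,}
#' so mean survival is \eqn{\lambda \Gamma(1 + 1/\alpha)}. Cost given
#' survival time t is gamma with shape `nu_k` and mean
#' \eqn{\mu_k(t) = \beta_k + \gamma_k t}: `beta` is the start-up cost of the
#' arm and `gamma` its cost accrual per unit time, both constrained positive
#' so that accrued cost grows with follow-up. Time and cost units are
#' whatever the user supplies (the shipped fixtures use years and $k); the
#' package never converts units.
#'
#' All ten parameters must be strictly positive. The object is a validated
#' immutable value list of class `"wg_params"`.
#'
#' @param alpha0,lambda0,nu0,beta0,gamma0 control-arm shape, scale, cost
#'   shape, start-up cost and cost accrual rate.
#' @param alpha1,lambda1,nu1,beta1,gamma1 treatment-arm counterparts.
#' @return An object of class `wg_params`.
#' @seealso [nn_params()], [inmb()], [simulate_trial()]
#' @examples
#' p <- wg_params(alpha0 = 0.75, lambda0 = 0.9, nu0 = 1.2,
#'                beta0 = 50, gamma0 = 75,
#'                alpha1 = 0.5, lambda1 = 1.5, nu1 = 3,
#'                beta1 = 100, gamma1 = 60)
#' inmb(p, wtp = 250)
#' @export
wg_params <- function(alpha0, lambda0, nu0, beta0, gamma0,
                      alpha1, lambda1, nu1, beta1, gamma1) {
  p <- list(alpha0 = alpha0, lambda0 = lambda0, nu0 = nu0,
            beta0 = beta0, gamma0 = gamma0,
            alpha1 = alpha1, lambda1 = lambda1, nu1 = nu1,
            beta1 = beta1, gamma1 = gamma1)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("wg_params: '", nm, "' must be a single strictly positive number",
           call. = FALSE)
  }
  structure(p, class = "wg_params")
}

#' Normal-normal model parameters
#'
#' Container for the ten parameters of the bivariate-normal joint
#' cost-effectiveness model. Survival time in arm k is
#' \eqn{N(\mu_k, \tau^2_{Tk})}; cost given time t is normal with mean
#' `theta1 + theta2 * t` (control) or `theta3 + theta4 * t` (treatment) and
#' variance `tauC0sq` / `tauC1sq`. The four variances must be strictly
#' positive; means and cost coefficients are unrestricted. The simulator
#' resamples the rare negative time or cost draw, so parameter sets implying
#' mostly-negative outcomes are rejected at generation time, not here.
#'
#' @param mu0,mu1 mean survival time per arm.
#' @param tauT0sq,tauT1sq survival-time variances per arm.
#' @param theta1,theta2 control-arm cost intercept and slope on time.
#' @param theta3,theta4 treatment-arm cost intercept and slope.
#' @param tauC0sq,tauC1sq conditional cost variances per arm.
#' @return An object of class `nn_params`.
#' @seealso [wg_params()], [nn_marginal_summary()]
#' @export
nn_params <- function(mu0, tauT0sq, theta1, theta2, tauC0sq,
                      mu1, tauT1sq, theta3, theta4, tauC1sq) {
  p <- list(mu0 = mu0, tauT0sq = tauT0sq, theta1 = theta1, theta2 = theta2,
            tauC0sq = tauC0sq, mu1 = mu1, tauT1sq = tauT1sq,
            theta3 = theta3, theta4 = theta4, tauC1sq = tauC1sq)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("nn_params: '", nm, "' must be a single finite number",
           call. = FALSE)
  }
  for (nm in c("tauT0sq", "tauT1sq", "tauC0sq", "tauC1sq"))
    if (p[[nm]] <= 0)
      stop("nn_params: variance '", nm, "' must be strictly positive",
           call. = FALSE)
  structure(p, class = "nn_params")
}

#' @export
print.wg_params <- function(x, ...) {
  cat("Weibull-gamma cost-effectiveness parameters\n")
  m <- rbind(control   = c(x$alpha0, x$lambda0, x$nu0, x$beta0, x$gamma0),
             treatment = c(x$alpha1, x$lambda1, x$nu1, x$beta1, x$gamma1))
  colnames(m) <- c("shape", "scale", "cost.shape", "startup", "accrual")
  print(m, ...)
  cat(sprintf("mean survival: control %.4f, treatment %.4f\n",
              weibull_mean(x$alpha0, x$lambda0),
              weibull_mean(x$alpha1, x$lambda1)))
  invisible(x)
}

#' @export
print.nn_params <- function(x, ...) {
  cat("Normal-normal cost-effectiveness parameters\n")
  m <- rbind(control   = c(x$mu0, sqrt(x$tauT0sq), x$theta1, x$theta2,
                           sqrt(x$tauC0sq)),
             treatment = c(x$mu1, sqrt(x$tauT1sq), x$theta3, x$theta4,
                           sqrt(x$tauC1sq)))
  colnames(m) <- c("mean.time", "sd.time", "cost.int", "cost.slope", "sd.cost")
  print(m, ...)
  invisible(x)
}

# arm-level views used throughout the samplers and simulators
wg_arm <- function(p, arm) {
  if (arm == 0L)
    list(alpha = p$alpha0, lambda = p$lambda0, nu = p$nu0,
         beta = p$beta0, gamma = p$gamma0)
  else
    list(alpha = p$alpha1, lambda = p$lambda1, nu = p$nu1,
         beta = p$beta1, gamma = p$gamma1)
}

nn_arm <- function(p, arm) {
  if (arm == 0L)
    list(mu = p$mu0, tauTsq = p$tauT0sq, a = p$theta1, b = p$theta2,
         tauCsq = p$tauC0sq)
  else
    list(mu = p$mu1, tauTsq = p$tauT1sq, a = p$theta3, b = p$theta4,
         tauCsq = p$tauC1sq)
}

check_arm <- function(arm) {
  if (!all(arm %in% c(0, 1)))
    stop("arm labels must be 0 (control) or 1 (treatment)", call. = FALSE)
  as.integer(arm)
}

#' Design values used by the shipped Weibull-gamma fixtures
#'
#' The ten fixed design values of the Weibull-gamma examples (time in years,
#' cost in $k): control Weibull(0.75, 0.9) survival with gamma costs of
#' shape 1.2 and mean 50 + 75 t; treatment Weibull(0.5, 1.5) with cost shape
#' 3 and mean 100 + 60 t. Under these values the expected INMB is
#' 1.93 WTP - 150 (to the displayed precision).
#'
#' @return A [wg_params()] object.
#' @export
wg_design_values <- function() {
  wg_params(alpha0 = 0.75, lambda0 = 0.9, nu0 = 1.2, beta0 = 50, gamma0 = 75,
            alpha1 = 0.5, lambda1 = 1.5, nu1 = 3, beta1 = 100, gamma1 = 60)
}

#' Design values used by the shipped normal-normal fixture
#'
#' Fixed design values of the bivariate-normal example (time in months,
#' cost in $k). Under these values the expected INMB is 8.5 WTP - 570.
#'
#' @return An [nn_params()] object.
#' @export
nn_design_values <- function() {
  nn_params(mu0 = 25.0, tauT0sq = 8.5^2, theta1 = 103.5, theta2 = 1.06,
            tauC0sq = 28.6^2,
            mu1 = 33.5, tauT1sq = 8.5^2, theta3 = 539.9, theta4 = 4.78,
            tauC1sq = 93.0^2)
}
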