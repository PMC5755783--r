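#' Simulate a two-arm cost-effectiveness trial
#'
#' Generates a balanced two-arm trial from either joint model under a
#' censoring mechanism, following the generative scheme of the design
#' algorithm: draw a latent survival time T from the arm's survival model
#' and an independent censoring time U from `spec`; if `T <= U` the record
#' is an event with observed time T and cost drawn from the conditional
#' cost model at T; otherwise the record is censored at U with the accrued
#' cost observed at U.
#'
#' Two conventions for the observed censored cost are available.
#' `"accrued"` (default) draws it from the model's conditional cost
#' distribution evaluated at the censoring time — cost accrual follows the
#' same law up to any observation time, so the observed cost
#' stochastically under-represents the latent total cost. `"scaled"` draws
#' the latent total cost at T and records the fraction `U/T` of it,
#' a deterministic linear-accrual reading of the same idea.
#'
#' For the normal-normal model, subjects whose latent time or cost draw is
#' non-positive are resampled (up to `max_retry` attempts per subject, then
#' an error names the offending arm), so returned records always have
#' strictly positive time and cost.
#'
#' @param params a [wg_params()] or [nn_params()] object; selects the model.
#' @param n_per_arm subjects per arm (the trial has `2 * n_per_arm` records).
#' @param spec a [censoring_spec()]; default no censoring.
#' @param censored_cost `"accrued"` or `"scaled"`, see Details.
#' @param max_retry resampling budget per subject (normal-normal only).
#' @return A [trial_data()] with `2 * n_per_arm` rows, control arm first.
#' @examples
#' set.seed(1)
#' d <- simulate_trial(wg_design_values(), n_per_arm = 100,
#'                     spec = censoring_spec("uniform_window",
#'                                           window_lo = 2.5,
#'                                           window_hi = 3.5))
#' mean(d$event == 0)  # censoring fraction
#' @export
simulate_trial <- function(params, n_per_arm,
                           spec = censoring_spec("none"),
                           censored_cost = c("accrued", "scaled"),
                           max_retry = 1000L) {
  UseMethod("simulate_trial")
}

#' @export
simulate_trial.wg_params <- function(params, n_per_arm,
                                     spec = censoring_spec("none"),
                                     censored_cost = c("accrued", "scaled"),
                                     max_retry = 1000L) {
  censored_cost <- match.arg(censored_cost)
  stopifnot(n_per_arm >= 1)
  sim_arm <- function(arm) {
    a <- wg_arm(params, arm)
    tt <- rweibull(n_per_arm, shape = a$alpha, scale = a$lambda)
    u <- draw_censoring_times(spec, n_per_arm)
    event <- as.integer(tt <= u)
    tobs <- pmin(tt, u)
    mu_at <- function(s) a$beta + a$gamma * s
    cobs <- rgamma(n_per_arm, shape = a$nu, rate = a$nu / mu_at(tobs))
    if (censored_cost == "scaled") {
      cens <- event == 0L
      if (any(cens)) {
        full <- rgamma(sum(cens), shape = a$nu, rate = a$nu / mu_at(tt[cens]))
        cobs[cens] <- full * u[cens] / tt[cens]
      }
    }
    list(time = tobs, cost = cobs, arm = rep(arm, n_per_arm), event = event)
  }
  a0 <- sim_arm(0L); a1 <- sim_arm(1L)
  trial_data(c(a0$time, a1$time), c(a0$cost, a1$cost),
             c(a0$arm, a1$arm), c(a0$event, a1$event))
}

#' @export
simulate_trial.nn_params <- function(params, n_per_arm,
                                     spec = censoring_spec("none"),
                                     censored_cost = c("accrued", "scaled"),
                                     max_retry = 1000L) {
  censored_cost <- match.arg(censored_cost)
  stopifnot(n_per_arm >= 1)
  sim_arm <- function(arm) {
    a <- nn_arm(params, arm)
    # latent (T, C_total) with positivity enforced by per-subject resampling
    tt <- numeric(n_per_arm); cc <- numeric(n_per_arm)
    todo <- seq_len(n_per_arm); tries <- 0L
    while (length(todo)) {
      if (tries >= max_retry)
        stop("simulate_trial: positivity resampling budget exhausted in arm ",
             arm, call. = FALSE)
      t_new <- rnorm(length(todo), a$mu, sqrt(a$tauTsq))
      c_new <- rnorm(length(todo), a$a + a$b * t_new, sqrt(a$tauCsq))
      ok <- t_new > 0 & c_new > 0
      tt[todo[ok]] <- t_new[ok]; cc[todo[ok]] <- c_new[ok]
      todo <- todo[!ok]; tries <- tries + 1L
    }
    u <- draw_censoring_times(spec, n_per_arm)
    event <- as.integer(tt <= u)
    tobs <- pmin(tt, u)
    cobs <- cc
    cens <- which(event == 0L)
    if (length(cens)) {
      if (censored_cost == "accrued") {
        # accrued cost at the censoring time, from the same conditional law
        cnew <- rnorm(length(cens), a$a + a$b * u[cens], sqrt(a$tauCsq))
        bad <- which(cnew <= 0); tries <- 0L
        while (length(bad)) {
          if (tries >= max_retry)
            stop("simulate_trial: positivity resampling budget exhausted in arm ",
                 arm, call. = FALSE)
          cnew[bad] <- rnorm(length(bad), a$a + a$b * u[cens][bad],
                             sqrt(a$tauCsq))
          bad <- bad[cnew[bad] <= 0]; tries <- tries + 1L
        }
        cobs[cens] <- cnew
      } else {
        cobs[cens] <- cc[cens] * u[cens] / tt[cens]
      }
    }
    list(time = tobs, cost = cobs, arm = rep(arm, n_per_arm), event = event)
  }
  a0 <- sim_arm(0L); a1 <- sim_arm(1L)
  trial_data(c(a0$time, a1$time), c(a0$cost, a1$cost),
             c(a0$arm, a1$arm), c(a0$event, a1$event))
}
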