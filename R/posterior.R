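#' Posterior draws of the incremental net monetary benefit
#'
#' Maps every retained posterior parameter draw through the model's INMB
#' function at willingness-to-pay `wtp` and reports the posterior
#' probability that the INMB is strictly positive. Ties at exactly zero
#' count as failures (the success rule is the strict inequality
#' `INMB > 0`).
#'
#' @param fit a [fit_trial()] result.
#' @param wtp scalar willingness to pay.
#' @return A list with `inmb_draws` (numeric vector, one per retained
#'   draw), `prob_positive`, and `wtp`.
#' @seealso [prob_ce()] for a whole WTP grid at once.
#' @export
posterior_inmb <- function(fit, wtp) {
  stopifnot(inherits(fit, "ce_fit"), is.numeric(wtp), length(wtp) == 1L,
            wtp >= 0)
  comp <- inmb_draw_components(fit)
  draws <- comp$d_effect * wtp - comp$d_cost
  list(inmb_draws = draws, prob_positive = mean(draws > 0), wtp = wtp)
}

#' Posterior probability of cost-effectiveness over a WTP grid
#'
#' `Pr(INMB > 0 | data)` for each value of a willingness-to-pay grid,
#' computed from one set of posterior draws (the INMB is a deterministic
#' map of the parameter draws, so a single fit serves every WTP).
#'
#' @param fit a [fit_trial()] result.
#' @param wtp_grid numeric vector of WTP values.
#' @return Named numeric vector of posterior probabilities.
#' @export
prob_ce <- function(fit, wtp_grid) {
  stopifnot(inherits(fit, "ce_fit"), is.numeric(wtp_grid), all(wtp_grid >= 0))
  comp <- inmb_draw_components(fit)
  vapply(wtp_grid,
         function(w) mean(comp$d_effect * w - comp$d_cost > 0),
         numeric(1)) |> setNames(wtp_grid)
}

# per-draw effectiveness and cost differences (vectorized over draws)
inmb_draw_components <- function(fit) {
  d <- fit$draws
  if (fit$model == "wg") {
    m0 <- d[, "lambda0"] * gamma(1 + 1 / d[, "alpha0"])
    m1 <- d[, "lambda1"] * gamma(1 + 1 / d[, "alpha1"])
    list(d_effect = m1 - m0,
         d_cost = (d[, "beta1"] + d[, "gamma1"] * m1) -
                  (d[, "beta0"] + d[, "gamma0"] * m0))
  } else {
    list(d_effect = d[, "mu1"] - d[, "mu0"],
         d_cost = (d[, "theta3"] + d[, "theta4"] * d[, "mu1"]) -
                  (d[, "theta1"] + d[, "theta2"] * d[, "mu0"]))
  }
}
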