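#' MCMC settings
#'
#' @param chains number of independent chains (default 3).
#' @param burn_in iterations discarded per chain (default 2000); the
#'   Weibull-gamma sampler adapts its random-walk step sizes only during
#'   burn-in and freezes them afterwards.
#' @param keep retained iterations per chain after burn-in (default 10000).
#' @param thin keep every `thin`-th retained iteration (default 1).
#' @param seed integer seed making the fit reproducible; `NULL` leaves the
#'   RNG state untouched.
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(chains = 3L, burn_in = 2000L, keep = 10000L,
                          thin = 1L, seed = NULL) {
  stopifnot(chains >= 1, burn_in >= 0, keep >= 100, thin >= 1)
  structure(list(chains = as.integer(chains), burn_in = as.integer(burn_in),
                 keep = as.integer(keep), thin = as.integer(thin),
                 seed = seed),
            class = "mcmc_settings")
}

#' Fit a cost-effectiveness model to (possibly censored) trial data
#'
#' Posterior sampling for either joint model by data-augmentation MCMC.
#' Each iteration alternates (i) imputation of the latent survival time and
#' latent total cost of every censored record from their joint conditional
#' given the observed censoring information — the latent time from the
#' survival density truncated to `(t_i, Inf)` and tilted by the conditional
#' cost survival function at the observed accrued cost, via an
#' independence Metropolis-Hastings step with an exact truncated-draw
#' proposal; the latent cost exactly, by inverse-CDF truncated sampling —
#' and (ii) parameter updates given the completed data. For the
#' Weibull-gamma model the parameter updates are adaptive log-scale
#' random-walk Metropolis steps (positivity is automatic on the log scale);
#' for the normal-normal model every full conditional is conjugate and is
#' drawn exactly (Gibbs).
#'
#' With no censored records the imputation step is skipped entirely, so the
#' sampler's target is exactly the complete-data posterior.
#'
#' @param data a [trial_data()] with both arms present.
#' @param prior a [wg_analysis_prior()] or [nn_analysis_prior()]; selects
#'   the model.
#' @param settings an [mcmc_settings()].
#' @param fix optional named list of parameters to hold fixed at given
#'   values (excluded from updating; mainly for validation studies).
#' @return An object of class `ce_fit` with elements
#'   \describe{
#'     \item{`draws`}{matrix of retained draws, one column per model
#'       parameter, stacked over chains;}
#'     \item{`chain`, `iter`}{chain id and within-chain index per row;}
#'     \item{`diagnostics`}{per-parameter split-chain scale reduction and
#'       effective sample size;}
#'     \item{`accept`}{mean Metropolis acceptance rates (WG only);}
#'     \item{`n_censored`, `augmented`}{censoring bookkeeping.}
#'   }
#'   A warning (also stored in `$convergence_warning`) is attached when any
#'   monitored scale reduction exceeds 1.05.
#' @examples
#' set.seed(42)
#' d <- simulate_trial(nn_design_values(), n_per_arm = 150)
#' f <- fit_trial(d, nn_analysis_prior(),
#'                mcmc_settings(chains = 2, burn_in = 200, keep = 500,
#'                              seed = 1))
#' posterior_inmb(f, wtp = 100)$prob_positive
#' @export
fit_trial <- function(data, prior, settings = mcmc_settings(), fix = NULL) {
  stopifnot(inherits(data, "trial_data"), inherits(settings, "mcmc_settings"))
  if (nrow(data) == 0L) stop("fit_trial: empty dataset", call. = FALSE)
  for (a in 0:1) {
    idx <- data$arm == a
    if (!any(idx))
      stop("fit_trial: arm ", a, " has no records", call. = FALSE)
    if (!any(data$event[idx] == 1L))
      stop("fit_trial: arm ", a, " is fully censored; the model cannot be ",
           "identified", call. = FALSE)
  }
  model <- if (inherits(prior, "wg_prior")) "wg"
           else if (inherits(prior, "nn_prior")) "nn"
           else stop("fit_trial: 'prior' must be wg_analysis_prior() or ",
                     "nn_analysis_prior()", call. = FALSE)
  par_names <- names(prior)
  if (!is.null(fix)) {
    bad <- setdiff(names(fix), par_names)
    if (length(bad))
      stop("fit_trial: unknown fixed parameter(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(settings$seed)) set.seed(settings$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, settings$chains)
  runner <- if (model == "wg") run_chain_wg else run_chain_nn
  chains <- lapply(seq_len(settings$chains), function(ch) {
    set.seed(chain_seeds[ch])
    runner(data, prior, settings, fix, jitter = (ch > 1L))
  })
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  n_kept <- nrow(chains[[1]]$draws)
  chain_id <- rep(seq_len(settings$chains), each = n_kept)
  free <- setdiff(par_names, names(fix))
  diag <- mcmc_diagnostics(draws, chain_id, free)
  accept <- if (model == "wg") {
    acc <- do.call(rbind, lapply(chains, `[[`, "accept"))
    colMeans(acc)
  } else NULL
  warn <- NULL
  if (any(diag$rhat[free] > 1.05, na.rm = TRUE)) {
    warn <- paste0("possible non-convergence: max split-chain Rhat = ",
                   sprintf("%.3f", max(diag$rhat[free], na.rm = TRUE)))
    warning(warn, call. = FALSE)
  }
  structure(list(draws = draws, chain = chain_id,
                 iter = rep(seq_len(n_kept), settings$chains),
                 model = model, prior = prior, settings = settings,
                 fix = fix, diagnostics = diag, accept = accept,
                 n_censored = sum(data$event == 0L),
                 augmented = any(data$event == 0L),
                 convergence_warning = warn),
            class = "ce_fit")
}

#' @export
print.ce_fit <- function(x, ...) {
  cat(sprintf("ce_fit (%s model): %d chains x %d retained draws, %d censored records %s\n",
              x$model, x$settings$chains, sum(x$chain == 1L), x$n_censored,
              if (x$augmented) "(augmented)" else ""))
  print(summary(x), ...)
  invisible(x)
}

#' @export
summary.ce_fit <- function(object, ...) {
  d <- object$draws
  out <- data.frame(
    mean = colMeans(d),
    sd = apply(d, 2, sd),
    `q2.5` = apply(d, 2, quantile, 0.025),
    `q97.5` = apply(d, 2, quantile, 0.975),
    rhat = object$diagnostics$rhat[colnames(d)],
    ess = object$diagnostics$ess[colnames(d)],
    check.names = FALSE)
  rownames(out) <- colnames(d)
  out
}

#' Write posterior draws and summary to CSV
#'
#' `write_fit` writes two files under `dir`: `draws.csv` (one column per
#' parameter plus `chain` and `iter`) and `summary.csv` (mean, sd, 2.5%,
#' 97.5%, scale reduction and effective size per parameter).
#'
#' @param fit a [fit_trial()] result.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "ce_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  draws <- data.frame(chain = fit$chain, iter = fit$iter, fit$draws,
                      check.names = FALSE)
  write.csv(draws, file.path(dir, "draws.csv"), row.names = FALSE)
  s <- summary(fit)
  write.csv(cbind(parameter = rownames(s), s),
            file.path(dir, "summary.csv"), row.names = FALSE)
  invisible(dir)
}

# split-chain Rhat (each chain halved) and a Geyer-style effective sample
# size from pooled, per-chain-centered autocorrelations
mcmc_diagnostics <- function(draws, chain_id, monitored) {
  p <- colnames(draws)
  rhat <- setNames(rep(NA_real_, length(p)), p)
  ess <- setNames(rep(NA_real_, length(p)), p)
  chains <- split(seq_len(nrow(draws)), chain_id)
  half_idx <- unlist(lapply(chains, function(ix) {
    h <- length(ix) %/% 2L
    list(ix[seq_len(h)], ix[(h + 1L):(2L * h)])
  }), recursive = FALSE)
  for (nm in monitored) {
    x <- draws[, nm]
    if (sd(x) == 0) { rhat[nm] <- 1; ess[nm] <- length(x); next }
    halves <- lapply(half_idx, function(ix) x[ix])
    m <- length(halves); n <- length(halves[[1]])
    means <- vapply(halves, mean, numeric(1))
    vars <- vapply(halves, var, numeric(1))
    W <- mean(vars); B <- n * var(means)
    vhat <- (n - 1) / n * W + B / n
    rhat[nm] <- if (W > 0) sqrt(vhat / W) else 1
    # ESS: average per-chain autocorrelation, initial-positive-sequence cut
    rho_sum <- 0
    lags <- min(200L, n - 2L)
    acs <- sapply(halves, function(h)
      stats::acf(h, lag.max = lags, plot = FALSE,
                 demean = TRUE)$acf[-1, 1, 1])
    rho <- rowMeans(acs)
    for (l in seq(1, length(rho) - 1, by = 2)) {
      pair <- rho[l] + rho[l + 1]
      if (is.na(pair) || pair < 0) break
      rho_sum <- rho_sum + pair
    }
    ess[nm] <- max(1, (m * n) / (1 + 2 * rho_sum))
  }
  list(rhat = rhat, ess = ess)
}
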