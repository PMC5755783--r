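#' Design specification for the sample-size determination loop
#'
#' Bundles everything the Monte-Carlo design algorithm needs: the model,
#' the design prior that generates trials, the analysis prior used to fit
#' each of them, the censoring mechanism, the willingness-to-pay and
#' sample-size grids, the replicate count `B`, the posterior success
#' threshold, and the required rejection proportion.
#'
#' @param design_prior a [design_prior()]; all-fixed descriptors give
#'   power, distributional ones give assurance.
#' @param analysis_prior a [wg_analysis_prior()] or [nn_analysis_prior()]
#'   consistent with the design prior's model.
#' @param censoring a [censoring_spec()].
#' @param wtp_grid sorted vector of willingness-to-pay values (default
#'   100 to 350 by 50, in cost units per time unit).
#' @param n_grid sorted vector of total sample sizes (split 1:1; an odd n
#'   puts the extra subject in the control arm).
#' @param B Monte-Carlo replicates per sample size (default 300).
#' @param success_prob posterior threshold: a replicate is a success at a
#'   given WTP when `Pr(INMB > 0 | data) > success_prob` (default 0.95).
#' @param target required rejection proportion for sample-size selection
#'   (default 0.8).
#' @param mcmc an [mcmc_settings()] used for every replicate fit.
#' @param seed integer seed for the whole design run.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(design_prior, analysis_prior,
                        censoring = censoring_spec("none"),
                        wtp_grid = seq(100, 350, by = 50),
                        n_grid, B = 300L, success_prob = 0.95,
                        target = 0.8, mcmc = mcmc_settings(), seed = 1L) {
  stopifnot(inherits(design_prior, "design_prior"),
            inherits(censoring, "censoring_spec"),
            inherits(mcmc, "mcmc_settings"),
            B >= 1, success_prob > 0, success_prob < 1,
            target > 0, target < 1,
            length(wtp_grid) >= 1, !is.unsorted(wtp_grid), all(wtp_grid >= 0),
            length(n_grid) >= 1, !is.unsorted(n_grid), all(n_grid >= 2))
  model <- design_prior$model
  ok <- (model == "wg" && inherits(analysis_prior, "wg_prior")) ||
        (model == "nn" && inherits(analysis_prior, "nn_prior"))
  if (!ok)
    stop("design_spec: analysis prior does not match the design prior's ",
         "model ('", model, "')", call. = FALSE)
  mode <- if (all(vapply(design_prior$descriptors,
                         function(d) d$kind == "fixed", logical(1))))
    "power" else "assurance"
  structure(list(model = model, mode = mode, design_prior = design_prior,
                 analysis_prior = analysis_prior, censoring = censoring,
                 wtp_grid = as.numeric(wtp_grid),
                 n_grid = as.integer(n_grid), B = as.integer(B),
                 success_prob = success_prob, target = target,
                 mcmc = mcmc, seed = as.integer(seed)),
            class = "design_spec")
}

#' Run the Monte-Carlo sample-size determination algorithm
#'
#' For every total sample size `n` in the grid and every replicate
#' `k = 1, ..., B`: draw a parameter set from the design prior, simulate a
#' censored trial of size `n`, fit it with the analysis prior, and record
#' for every WTP on the grid whether `Pr(INMB > 0 | data)` exceeded the
#' success threshold. The rejection proportion
#' \deqn{r^{(n)} = \frac{1}{B} \sum_{k=1}^{B}
#'   I\{\Pr(INMB > 0 | WTP, d^{(n,k)}) > 1 - \phi\}}
#' estimates power (all-fixed design prior) or assurance (distributional
#' design prior). One posterior fit per replicate serves the whole WTP
#' grid. Each replicate runs on its own pre-drawn RNG stream, so results
#' are identical for any worker count.
#'
#' @param spec a [design_spec()].
#' @param jobs number of worker processes (forked via
#'   [parallel::mclapply()]; results are worker-count invariant).
#' @param verbose print per-sample-size progress?
#' @return An object of class `design_result`: rejection-proportion matrix
#'   `r` (`n_grid` x `wtp_grid`), Monte-Carlo standard errors `mc_se`,
#'   per-WTP selected sizes `n_star`, the convergence-failure rate, and
#'   the spec.
#' @examples
#' \donttest{
#' sp <- design_spec(design_prior_fixed(nn_design_values()),
#'                   nn_analysis_prior(),
#'                   censoring_spec("normal_window", mean = 36, sd = 2.4),
#'                   n_grid = c(50, 100), B = 20,
#'                   mcmc = mcmc_settings(chains = 1, burn_in = 200,
#'                                        keep = 500),
#'                   seed = 7)
#' res <- run_design(sp)
#' select_sample_size(res, wtp = 250)
#' }
#' @export
run_design <- function(spec, jobs = 1L, verbose = FALSE) {
  stopifnot(inherits(spec, "design_spec"))
  set.seed(spec$seed)
  n_cells <- length(spec$n_grid) * spec$B
  cell_seeds <- matrix(sample.int(.Machine$integer.max - 1L, n_cells),
                       nrow = spec$B)
  one_rep <- function(n_idx, k) {
    set.seed(cell_seeds[k, n_idx])
    n_total <- spec$n_grid[n_idx]
    theta <- draw_design_params(spec$design_prior)
    n1 <- n_total %/% 2L
    n0 <- n_total - n1
    d <- sim_unbalanced(theta, n0, n1, spec$censoring)
    fit <- withCallingHandlers(
      tryCatch(
        fit_trial(d, spec$analysis_prior,
                  mcmc_settings(chains = spec$mcmc$chains,
                                burn_in = spec$mcmc$burn_in,
                                keep = spec$mcmc$keep,
                                thin = spec$mcmc$thin, seed = NULL)),
        error = function(e)
          stop("run_design: fit failed at n = ", n_total, ", replicate ", k,
               " (theta: ",
               paste(sprintf("%s=%.4g", names(unclass(theta)),
                             unlist(unclass(theta))), collapse = ", "),
               "): ", conditionMessage(e), call. = FALSE)),
      warning = function(w) invokeRestart("muffleWarning"))
    pr <- prob_ce(fit, spec$wtp_grid)
    list(ind = as.integer(pr > spec$success_prob),
         conv_fail = !is.null(fit$convergence_warning))
  }
  r <- matrix(NA_real_, length(spec$n_grid), length(spec$wtp_grid),
              dimnames = list(spec$n_grid, spec$wtp_grid))
  conv_fail <- 0L
  for (n_idx in seq_along(spec$n_grid)) {
    reps <- if (jobs > 1L)
      parallel::mclapply(seq_len(spec$B), function(k) one_rep(n_idx, k),
                         mc.cores = jobs)
    else lapply(seq_len(spec$B), function(k) one_rep(n_idx, k))
    bad <- which(!vapply(reps, is.list, logical(1)))
    if (length(bad))
      stop("run_design: worker failure at n = ", spec$n_grid[n_idx],
           ", replicate ", bad[1], ": ",
           paste(as.character(reps[[bad[1]]]), collapse = " "),
           call. = FALSE)
    ind <- do.call(rbind, lapply(reps, `[[`, "ind"))
    r[n_idx, ] <- colMeans(ind)
    conv_fail <- conv_fail + sum(vapply(reps, `[[`, logical(1), "conv_fail"))
    if (verbose)
      message(sprintf("n = %d: r = %s", spec$n_grid[n_idx],
                      paste(sprintf("%.2f", r[n_idx, ]), collapse = " ")))
  }
  mc_se <- sqrt(r * (1 - r) / spec$B)
  n_star <- vapply(seq_along(spec$wtp_grid), function(j) {
    hit <- which(r[, j] >= spec$target)
    if (length(hit)) spec$n_grid[min(hit)] else NA_integer_
  }, integer(1))
  names(n_star) <- spec$wtp_grid
  structure(list(r = r, mc_se = mc_se, mode = spec$mode, n_star = n_star,
                 B = spec$B,
                 conv_fail_rate = conv_fail / (spec$B * length(spec$n_grid)),
                 spec = spec),
            class = "design_result")
}

# balanced-arms helper allowing an unequal split for odd total n
sim_unbalanced <- function(theta, n0, n1, spec_cens) {
  if (n0 == n1) return(simulate_trial(theta, n0, spec_cens))
  d <- simulate_trial(theta, max(n0, n1), spec_cens)
  if (n1 < n0) {
    idx1 <- which(d$arm == 1L)
    drop <- idx1[seq_len(length(idx1) - n1)]
    d <- d[-drop, , drop = FALSE]
  }
  trial_data(d$time, d$cost, d$arm, d$event)
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("design_result (%s mode): B = %d, %.1f%% convergence flags\n",
              x$mode, x$B, 100 * x$conv_fail_rate))
  cat("rejection proportion r(n) [rows: total n, cols: WTP]:\n")
  print(round(x$r, 3))
  cat("selected n* per WTP (target r >=", x$spec$target, "):\n")
  print(x$n_star)
  invisible(x)
}

#' Smallest sample size meeting the design target
#'
#' The smallest total sample size on the grid whose rejection proportion
#' reaches the target (`>=`, so a proportion exactly at the target
#' qualifies). Returns `NA` — with the best achieved proportion reported
#' in a message — when no grid size reaches it.
#'
#' @param result a [run_design()] result.
#' @param wtp a WTP value present in the grid.
#' @return The selected total sample size, or `NA_integer_`.
#' @export
select_sample_size <- function(result, wtp) {
  stopifnot(inherits(result, "design_result"))
  j <- match(wtp, result$spec$wtp_grid)
  if (is.na(j))
    stop("select_sample_size: wtp = ", wtp, " is not on the design grid",
         call. = FALSE)
  hit <- which(result$r[, j] >= result$spec$target)
  if (!length(hit)) {
    message("no grid sample size reaches the target; max r = ",
            sprintf("%.3f", max(result$r[, j])))
    return(NA_integer_)
  }
  result$spec$n_grid[min(hit)]
}

#' Write a design result to disk
#'
#' Writes a long-format CSV `design_result.csv` with columns
#' `n,wtp,mode,r,mc_se,B` and a JSON manifest `manifest.json` recording
#' the full specification, seed and convergence-failure rate.
#'
#' @param result a [run_design()] result.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_design_result <- function(result, dir) {
  stopifnot(inherits(result, "design_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- expand.grid(n = result$spec$n_grid, wtp = result$spec$wtp_grid)
  long$mode <- result$mode
  long$r <- as.vector(result$r)
  long$mc_se <- as.vector(result$mc_se)
  long$B <- result$B
  write.csv(long, file.path(dir, "design_result.csv"), row.names = FALSE)
  sp <- result$spec
  manifest <- list(
    model = sp$model, mode = sp$mode, seed = sp$seed, B = sp$B,
    success_prob = sp$success_prob, target = sp$target,
    wtp_grid = sp$wtp_grid, n_grid = sp$n_grid,
    censoring = sp$censoring[!vapply(sp$censoring, is.null, logical(1))],
    mcmc = unclass(sp$mcmc)[c("chains", "burn_in", "keep", "thin")],
    design_prior = lapply(sp$design_prior$descriptors, unclass),
    analysis_prior = lapply(sp$analysis_prior, as.numeric),
    conv_fail_rate = result$conv_fail_rate,
    n_star = as.list(setNames(result$n_star, sp$wtp_grid)),
    package_version = as.character(utils::packageVersion("cedesign")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Plot rejection-proportion curves
#'
#' One curve of `r(n)` against total sample size per willingness-to-pay
#' value, with the target proportion as a horizontal reference line.
#'
#' @param x a [run_design()] result.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.design_result <- function(x, ...) {
  matplot(x$spec$n_grid, x$r, type = "b", pch = 16, lty = 1,
          xlab = "total sample size n",
          ylab = sprintf("r(n): %s", x$mode), ylim = c(0, 1), ...)
  abline(h = x$spec$target, lty = 2, col = "grey40")
  legend("bottomright", legend = paste("WTP", x$spec$wtp_grid),
         col = seq_along(x$spec$wtp_grid), lty = 1, pch = 16, bty = "n",
         cex = 0.8)
  invisible(x)
}
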