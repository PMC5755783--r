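# Weibull-gamma data-augmentation sampler.
#
# Parameter updates are single-site random-walk Metropolis on the log
# scale (positivity is automatic; the Jacobian term log(x) is included).
# Step sizes adapt toward a 0.44 acceptance rate during burn-in only and
# are frozen afterwards, preserving detailed balance for the retained
# draws. Latent survival times for censored records are refreshed each
# iteration by an independence MH step whose proposal is an exact draw
# from the Weibull truncated to (t_i, Inf); the acceptance ratio is the
# ratio of cost-survival tilts S_C|T(c_i | t*). Latent total costs are
# then exact truncated-gamma draws given the latent time.

run_chain_wg <- function(data, prior, settings, fix, jitter = FALSE) {
  arm_dat <- lapply(0:1, function(a) {
    idx <- which(data$arm == a)
    list(t = data$time[idx], c = data$cost[idx],
         cens = which(data$event[idx] == 0L))
  })
  par <- wg_init(data)
  if (jitter) par <- par * exp(rnorm(10, 0, 0.05))
  if (!is.null(fix)) par[names(fix)] <- unlist(fix)
  free <- setdiff(names(par), names(fix))

  # persistent latent state per arm (NULL when uncensored)
  lat <- lapply(arm_dat, function(ad) {
    if (length(ad$cens))
      list(t = ad$t[ad$cens] * 1.5, c = ad$c[ad$cens] * 1.5)
    else NULL
  })

  step <- setNames(rep(0.25, 10), names(par))
  acc_count <- setNames(numeric(10), names(par))
  acc_window <- setNames(numeric(10), names(par))
  window <- 0L

  # hoisted name tables: one row per arm
  nm_time <- lapply(1:2, function(a)
    paste0(c("alpha", "lambda"), a - 1L))
  nm_cost <- lapply(1:2, function(a)
    paste0(c("nu", "beta", "gamma"), a - 1L))
  upd_time <- lapply(nm_time, function(v) v[v %in% free])
  upd_cost <- lapply(nm_cost, function(v) v[v %in% free])
  nm_arm <- lapply(1:2, function(a)
    paste0(c("alpha", "lambda", "nu", "beta", "gamma"), a - 1L))

  n_iter <- settings$burn_in + settings$keep
  kept <- settings$keep %/% settings$thin
  draws <- matrix(NA_real_, kept, 10, dimnames = list(NULL, names(par)))
  krow <- 0L

  prior_ld <- function(nm, x)
    dgamma(x, shape = prior[[nm]][1], rate = prior[[nm]][2], log = TRUE)

  wll <- function(t, alpha, lambda)
    sum(dweibull(t, shape = alpha, scale = lambda, log = TRUE))
  cll <- function(cc, t, nu, beta, gam)
    sum(dgamma(cc, shape = nu, rate = nu / (beta + gam * t), log = TRUE))

  for (it in seq_len(n_iter)) {
    adapting <- it <= settings$burn_in
    # --- (i) imputation of censored records -------------------------------
    for (a in 1:2) {
      if (is.null(lat[[a]])) next
      ad <- arm_dat[[a]]
      av <- par[nm_arm[[a]]]
      alpha <- av[[1]]; lambda <- av[[2]]; nu <- av[[3]]
      beta <- av[[4]]; gam <- av[[5]]
      tc <- ad$t[ad$cens]; cc <- ad$c[ad$cens]
      # exact truncated-Weibull proposal via inverse survival transform
      prop <- lambda * ((tc / lambda)^alpha - log(runif(length(tc))))^(1 / alpha)
      tilt <- function(u)
        pgamma(cc, shape = nu, rate = nu / (beta + gam * u),
               lower.tail = FALSE, log.p = TRUE)
      la <- tilt(prop) - tilt(lat[[a]]$t)
      take <- log(runif(length(tc))) < la
      lat[[a]]$t[take] <- prop[take]
      # exact truncated-gamma cost given the latent time
      mu <- beta + gam * lat[[a]]$t
      p0 <- pgamma(cc, shape = nu, rate = nu / mu)
      u <- p0 + runif(length(cc)) * (1 - p0)
      cls <- qgamma(pmin(u, 1 - 1e-16), shape = nu, rate = nu / mu)
      lat[[a]]$c <- pmax(cls, cc * (1 + 1e-12))
    }
    # completed data
    tf <- lapply(1:2, function(a) {
      t <- arm_dat[[a]]$t
      if (!is.null(lat[[a]])) t[arm_dat[[a]]$cens] <- lat[[a]]$t
      t
    })
    cf <- lapply(1:2, function(a) {
      cc <- arm_dat[[a]]$c
      if (!is.null(lat[[a]])) cc[arm_dat[[a]]$cens] <- lat[[a]]$c
      cc
    })
    # --- (ii) parameter updates ------------------------------------------
    for (a in 1:2) {
      nm_a <- nm_time[[a]][1]; nm_l <- nm_time[[a]][2]
      nm_n <- nm_cost[[a]][1]; nm_b <- nm_cost[[a]][2]
      nm_g <- nm_cost[[a]][3]
      cur_wll <- wll(tf[[a]], par[[nm_a]], par[[nm_l]])
      for (nm in upd_time[[a]]) {
        old <- par[[nm]]
        new <- old * exp(rnorm(1, 0, step[[nm]]))
        par_new <- par; par_new[[nm]] <- new
        new_wll <- wll(tf[[a]], par_new[[nm_a]], par_new[[nm_l]])
        la <- new_wll + prior_ld(nm, new) + log(new) -
              (cur_wll + prior_ld(nm, old) + log(old))
        if (is.finite(la) && log(runif(1)) < la) {
          par <- par_new; cur_wll <- new_wll
          acc_count[[nm]] <- acc_count[[nm]] + 1
          acc_window[[nm]] <- acc_window[[nm]] + 1
        }
      }
      cur_cll <- cll(cf[[a]], tf[[a]], par[[nm_n]], par[[nm_b]], par[[nm_g]])
      for (nm in upd_cost[[a]]) {
        old <- par[[nm]]
        new <- old * exp(rnorm(1, 0, step[[nm]]))
        par_new <- par; par_new[[nm]] <- new
        new_cll <- cll(cf[[a]], tf[[a]], par_new[[nm_n]], par_new[[nm_b]],
                       par_new[[nm_g]])
        la <- new_cll + prior_ld(nm, new) + log(new) -
              (cur_cll + prior_ld(nm, old) + log(old))
        if (is.finite(la) && log(runif(1)) < la) {
          par <- par_new; cur_cll <- new_cll
          acc_count[[nm]] <- acc_count[[nm]] + 1
          acc_window[[nm]] <- acc_window[[nm]] + 1
        }
      }
    }
    # --- adaptation (burn-in only) ---------------------------------------
    if (adapting) {
      window <- window + 1L
      if (window == 25L) {
        rate <- acc_window / 25
        step[free] <- pmin(3, pmax(0.01,
          step[free] * exp(0.6 * (rate[free] - 0.44))))
        acc_window[] <- 0; window <- 0L
      }
    } else if (((it - settings$burn_in) %% settings$thin) == 0L) {
      krow <- krow + 1L
      draws[krow, ] <- par
    }
  }
  list(draws = draws[seq_len(krow), , drop = FALSE],
       accept = acc_count / n_iter)
}

# moment-based starting values: Weibull shape from the coefficient of
# variation of uncensored times, cost coefficients from a linear fit
wg_init <- function(data) {
  par <- numeric(0)
  for (k in 0:1) {
    idx <- data$arm == k
    tu <- data$time[idx & data$event == 1L]
    if (length(tu) < 3L) tu <- data$time[idx]
    cv <- sd(tu) / mean(tu)
    if (!is.finite(cv) || cv <= 0) cv <- 1
    alpha <- tryCatch(
      uniroot(function(a) gamma(1 + 2 / a) / gamma(1 + 1 / a)^2 - 1 - cv^2,
              interval = c(0.12, 20))$root,
      error = function(e) 1)
    lambda <- mean(tu) / gamma(1 + 1 / alpha)
    cu <- data$cost[idx & data$event == 1L]
    tu2 <- data$time[idx & data$event == 1L]
    if (length(cu) < 3L) { cu <- data$cost[idx]; tu2 <- data$time[idx] }
    cfit <- tryCatch(coef(lm(cu ~ tu2)), error = function(e) c(NA, NA))
    beta <- if (is.finite(cfit[1]) && cfit[1] > 0) cfit[1]
            else 0.5 * mean(cu)
    gam <- if (is.finite(cfit[2]) && cfit[2] > 0) cfit[2]
           else 0.5 * mean(cu) / mean(tu2)
    mu <- beta + gam * tu2
    nu <- 1 / mean(((cu - mu) / mu)^2)
    if (!is.finite(nu)) nu <- 1
    nu <- min(max(nu, 0.1), 100)
    par <- c(par, setNames(c(alpha, lambda, nu, beta, gam),
                           paste0(c("alpha", "lambda", "nu", "beta", "gamma"),
                                  k)))
  }
  # match analysis-prior ordering
  par[c("alpha0", "lambda0", "nu0", "alpha1", "lambda1", "nu1",
        "beta0", "gamma0", "beta1", "gamma1")]
}
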