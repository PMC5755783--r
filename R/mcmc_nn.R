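# Normal-normal data-augmentation sampler.
#
# Every full conditional of the completed-data model is conjugate, so
# parameter updates are exact Gibbs draws: normal for the arm means and
# the cost intercepts/slopes, inverse-gamma for the four variances.
# Censored records are augmented exactly as in the Weibull-gamma sampler:
# latent time by independence MH with an exact truncated-normal proposal
# and a cost-survival tilt, latent total cost by exact truncated-normal
# inverse-CDF sampling given the latent time.

run_chain_nn <- function(data, prior, settings, fix, jitter = FALSE) {
  arm_dat <- lapply(0:1, function(a) {
    idx <- which(data$arm == a)
    list(t = data$time[idx], c = data$cost[idx],
         cens = which(data$event[idx] == 0L))
  })
  par <- nn_init(data)
  if (jitter) {
    loc <- c("mu0", "mu1", "theta1", "theta2", "theta3", "theta4")
    par[loc] <- par[loc] + rnorm(6, 0, 0.05 * (abs(par[loc]) + 1))
    vv <- c("tauT0sq", "tauT1sq", "tauC0sq", "tauC1sq")
    par[vv] <- par[vv] * exp(rnorm(4, 0, 0.1))
  }
  if (!is.null(fix)) par[names(fix)] <- unlist(fix)
  free <- setdiff(names(par), names(fix))

  lat <- lapply(arm_dat, function(ad) {
    if (length(ad$cens))
      list(t = ad$t[ad$cens] + 1, c = ad$c[ad$cens] + 1)
    else NULL
  })

  n_iter <- settings$burn_in + settings$keep
  kept <- settings$keep %/% settings$thin
  draws <- matrix(NA_real_, kept, 10, dimnames = list(NULL, names(par)))
  krow <- 0L

  arm_names <- function(k)
    if (k == 0L) c(mu = "mu0", tauT = "tauT0sq", a = "theta1", b = "theta2",
                   tauC = "tauC0sq")
    else c(mu = "mu1", tauT = "tauT1sq", a = "theta3", b = "theta4",
           tauC = "tauC1sq")

  rinvgamma <- function(shape, rate) 1 / rgamma(1, shape = shape, rate = rate)

  for (it in seq_len(n_iter)) {
    # --- (i) imputation ---------------------------------------------------
    for (a in 1:2) {
      if (is.null(lat[[a]])) next
      ad <- arm_dat[[a]]
      nm <- arm_names(a - 1L)
      mu <- par[[nm["mu"]]]; sdT <- sqrt(par[[nm["tauT"]]])
      ia <- par[[nm["a"]]]; sl <- par[[nm["b"]]]
      sdC <- sqrt(par[[nm["tauC"]]])
      tc <- ad$t[ad$cens]; cc <- ad$c[ad$cens]
      # exact truncated-normal proposal on (t_i, Inf)
      p0 <- pnorm(tc, mu, sdT)
      u <- p0 + runif(length(tc)) * (1 - p0)
      prop <- qnorm(pmin(u, 1 - 1e-16), mu, sdT)
      prop <- pmax(prop, tc + 1e-12)
      tilt <- function(s)
        pnorm(cc, ia + sl * s, sdC, lower.tail = FALSE, log.p = TRUE)
      la <- tilt(prop) - tilt(lat[[a]]$t)
      take <- log(runif(length(tc))) < la
      lat[[a]]$t[take] <- prop[take]
      # exact truncated-normal latent total cost
      m <- ia + sl * lat[[a]]$t
      q0 <- pnorm(cc, m, sdC)
      v <- q0 + runif(length(cc)) * (1 - q0)
      cls <- qnorm(pmin(v, 1 - 1e-16), m, sdC)
      lat[[a]]$c <- pmax(cls, cc + 1e-12)
    }
    # --- (ii) conjugate parameter updates --------------------------------
    for (a in 1:2) {
      ad <- arm_dat[[a]]
      nm <- arm_names(a - 1L)
      t <- ad$t; cc <- ad$c
      if (!is.null(lat[[a]])) { t[ad$cens] <- lat[[a]]$t
                                cc[ad$cens] <- lat[[a]]$c }
      n <- length(t)
      # mean survival time
      if (nm["mu"] %in% free) {
        pm <- prior[[nm["mu"]]][1]; pv <- prior[[nm["mu"]]][2]
        prec <- n / par[[nm["tauT"]]] + 1 / pv
        mn <- (sum(t) / par[[nm["tauT"]]] + pm / pv) / prec
        par[[nm["mu"]]] <- rnorm(1, mn, sqrt(1 / prec))
      }
      # survival-time variance
      if (nm["tauT"] %in% free) {
        h <- prior[[nm["tauT"]]]
        par[[nm["tauT"]]] <- rinvgamma(h[1] + n / 2,
                                       h[2] + sum((t - par[[nm["mu"]]])^2) / 2)
      }
      # cost intercept given slope
      if (nm["a"] %in% free) {
        pm <- prior[[nm["a"]]][1]; pv <- prior[[nm["a"]]][2]
        r <- cc - par[[nm["b"]]] * t
        prec <- n / par[[nm["tauC"]]] + 1 / pv
        mn <- (sum(r) / par[[nm["tauC"]]] + pm / pv) / prec
        par[[nm["a"]]] <- rnorm(1, mn, sqrt(1 / prec))
      }
      # cost slope given intercept
      if (nm["b"] %in% free) {
        pm <- prior[[nm["b"]]][1]; pv <- prior[[nm["b"]]][2]
        r <- cc - par[[nm["a"]]]
        prec <- sum(t^2) / par[[nm["tauC"]]] + 1 / pv
        mn <- (sum(t * r) / par[[nm["tauC"]]] + pm / pv) / prec
        par[[nm["b"]]] <- rnorm(1, mn, sqrt(1 / prec))
      }
      # conditional cost variance
      if (nm["tauC"] %in% free) {
        h <- prior[[nm["tauC"]]]
        resid <- cc - par[[nm["a"]]] - par[[nm["b"]]] * t
        par[[nm["tauC"]]] <- rinvgamma(h[1] + n / 2,
                                       h[2] + sum(resid^2) / 2)
      }
    }
    if (it > settings$burn_in &&
        ((it - settings$burn_in) %% settings$thin) == 0L) {
      krow <- krow + 1L
      draws[krow, ] <- par
    }
  }
  list(draws = draws[seq_len(krow), , drop = FALSE], accept = NULL)
}

nn_init <- function(data) {
  par <- numeric(0)
  for (k in 0:1) {
    idx <- data$arm == k
    tu <- data$time[idx & data$event == 1L]
    cu <- data$cost[idx & data$event == 1L]
    if (length(tu) < 3L) { tu <- data$time[idx]; cu <- data$cost[idx] }
    cfit <- tryCatch(coef(lm(cu ~ tu)), error = function(e) c(mean(cu), 0))
    b <- if (is.finite(cfit[2])) cfit[2] else 0
    a <- if (is.finite(cfit[1])) cfit[1] else mean(cu)
    resid <- cu - a - b * tu
    par <- c(par, setNames(c(mean(tu), max(var(tu), 1e-6), a, b,
                             max(var(resid), 1e-6)),
                           if (k == 0L) c("mu0", "tauT0sq", "theta1",
                                          "theta2", "tauC0sq")
                           else c("mu1", "tauT1sq", "theta3", "theta4",
                                  "tauC1sq")))
  }
  par[c("mu0", "mu1", "theta1", "theta2", "theta3", "theta4",
        "tauT0sq", "tauT1sq", "tauC0sq", "tauC1sq")]
}
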