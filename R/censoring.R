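#' Censoring-time mechanism
#'
#' Generative description of the censoring-time distribution applied to a
#' simulated trial. Four mechanisms are provided:
#' \describe{
#'   \item{`"none"`}{no censoring; censoring times are `+Inf`.}
#'   \item{`"uniform_window"`}{study-end censoring uniform on
#'     `(window_lo, window_hi)` — e.g. a 12-month accrual period with
#'     average follow-up 3 years gives a 2.5-3.5 window.}
#'   \item{`"dropout_mixture"`}{with probability `1 - dropout_prob` the
#'     study-end window above; with probability `dropout_prob` early
#'     dropout uniform on `(0, dropout_hi)`. Far more variable than the
#'     plain window: it can censor subjects at very short follow-up.}
#'   \item{`"normal_window"`}{study-end time normal with mean `mean` and sd
#'     `sd`; non-positive draws are redrawn.}
#'   \item{`"exponential_dropout"`}{with probability `1 - dropout_prob` the
#'     study-end window; with probability `dropout_prob` an exponential
#'     dropout time with rate `rate`. Provided as an alternative heavy
#'     early-censoring mechanism.}
#' }
#'
#' @param kind one of the mechanism names above.
#' @param window_lo,window_hi bounds of the uniform study-end window.
#' @param dropout_prob probability of early dropout (mixture kinds).
#' @param dropout_hi upper bound of the uniform early-dropout time.
#' @param mean,sd parameters of the normal study-end time.
#' @param rate rate of the exponential dropout time.
#' @return An object of class `censoring_spec`.
#' @examples
#' censoring_spec("uniform_window", window_lo = 2.5, window_hi = 3.5)
#' censoring_spec("dropout_mixture", window_lo = 2.5, window_hi = 3.5,
#'                dropout_prob = 0.2, dropout_hi = 2.5)
#' @export
censoring_spec <- function(kind = c("none", "uniform_window",
                                    "dropout_mixture", "normal_window",
                                    "exponential_dropout"),
                           window_lo = NULL, window_hi = NULL,
                           dropout_prob = NULL, dropout_hi = NULL,
                           mean = NULL, sd = NULL, rate = NULL) {
  kind <- match.arg(kind)
  spec <- list(kind = kind, window_lo = window_lo, window_hi = window_hi,
               dropout_prob = dropout_prob, dropout_hi = dropout_hi,
               mean = mean, sd = sd, rate = rate)
  need <- function(field) {
    v <- spec[[field]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("censoring_spec: '", field, "' must be supplied for kind '",
           kind, "'", call. = FALSE)
    v
  }
  if (kind %in% c("uniform_window", "dropout_mixture",
                  "exponential_dropout")) {
    lo <- need("window_lo"); hi <- need("window_hi")
    if (lo < 0 || lo >= hi)
      stop("censoring_spec: need 0 <= window_lo < window_hi", call. = FALSE)
  }
  if (kind %in% c("dropout_mixture", "exponential_dropout")) {
    p <- need("dropout_prob")
    if (p < 0 || p > 1)
      stop("censoring_spec: 'dropout_prob' must lie in [0, 1]",
           call. = FALSE)
  }
  if (kind == "dropout_mixture" && need("dropout_hi") <= 0)
    stop("censoring_spec: 'dropout_hi' must be positive", call. = FALSE)
  if (kind == "exponential_dropout" && need("rate") <= 0)
    stop("censoring_spec: 'rate' must be positive", call. = FALSE)
  if (kind == "normal_window") {
    need("mean")
    if (need("sd") <= 0)
      stop("censoring_spec: 'sd' must be positive", call. = FALSE)
  }
  structure(spec, class = "censoring_spec")
}

#' @export
print.censoring_spec <- function(x, ...) {
  cat("censoring mechanism:", x$kind, "\n")
  flds <- x[!vapply(x, is.null, logical(1))]
  flds$kind <- NULL
  if (length(flds))
    cat(paste(names(flds), unlist(flds), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Draw censoring times
#'
#' Draws `n` i.i.d. censoring times from a [censoring_spec()] mechanism.
#' The `"none"` mechanism returns `+Inf` so downstream code can always take
#' `min(T, U)`.
#'
#' @param spec a [censoring_spec()].
#' @param n number of draws.
#' @return Numeric vector of length `n`, strictly positive (or `Inf`).
#' @export
draw_censoring_times <- function(spec, n) {
  stopifnot(inherits(spec, "censoring_spec"), n >= 0)
  switch(spec$kind,
    none = rep(Inf, n),
    uniform_window = runif(n, spec$window_lo, spec$window_hi),
    dropout_mixture = {
      u <- runif(n, spec$window_lo, spec$window_hi)
      drop <- runif(n) < spec$dropout_prob
      u[drop] <- runif(sum(drop), 0, spec$dropout_hi)
      # guard against a zero draw, which would violate t > 0
      pmax(u, .Machine$double.eps)
    },
    normal_window = {
      u <- rnorm(n, spec$mean, spec$sd)
      bad <- which(u <= 0)
      while (length(bad)) {
        u[bad] <- rnorm(length(bad), spec$mean, spec$sd)
        bad <- bad[u[bad] <= 0]
      }
      u
    },
    exponential_dropout = {
      u <- runif(n, spec$window_lo, spec$window_hi)
      drop <- runif(n) < spec$dropout_prob
      u[drop] <- rexp(sum(drop), rate = spec$rate)
      pmax(u, .Machine$double.eps)
    })
}
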