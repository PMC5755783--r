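#' Analysis (fitting) priors
#'
#' Prior distributions used when fitting a simulated or real dataset.
#'
#' For the Weibull-gamma model every parameter carries an independent
#' gamma(shape, rate) prior; the defaults are the diffuse gamma(0.1, 0.1)
#' (mean 1) on the shape and scale parameters and gamma(10, 0.1) (mean 100)
#' on the cost intercepts and slopes, weakly centered near typical cost
#' magnitudes. For the normal-normal model, means and cost coefficients
#' carry normal(mean, variance) priors — default normal(0, 10^4), diffuse
#' on the scale of the data — and variances carry inverse-gamma(shape,
#' rate) priors, default IG(0.01, 0.01) for time variances and
#' IG(0.001, 0.001) for cost variances.
#'
#' Every entry may be overridden via `...` with a numeric vector of the two
#' hyperparameters, e.g. `wg_analysis_prior(alpha0 = c(1, 1))`.
#'
#' @param ... named hyperparameter overrides, each `c(par1, par2)`.
#' @return A named list of class `wg_prior` / `nn_prior`; each element is
#'   `c(shape, rate)` (gamma), `c(mean, var)` (normal) or `c(shape, rate)`
#'   (inverse-gamma) as documented above.
#' @export
wg_analysis_prior <- function(...) {
  pr <- list()
  for (nm in c("alpha0", "lambda0", "nu0", "alpha1", "lambda1", "nu1"))
    pr[[nm]] <- c(shape = 0.1, rate = 0.1)
  for (nm in c("beta0", "gamma0", "beta1", "gamma1"))
    pr[[nm]] <- c(shape = 10, rate = 0.1)
  pr <- override_prior(pr, list(...), "wg_analysis_prior")
  for (nm in names(pr))
    if (any(pr[[nm]] <= 0))
      stop("wg_analysis_prior: hyperparameters for '", nm,
           "' must be positive", call. = FALSE)
  structure(pr, class = "wg_prior")
}

#' @rdname wg_analysis_prior
#' @export
nn_analysis_prior <- function(...) {
  pr <- list()
  for (nm in c("mu0", "mu1", "theta1", "theta2", "theta3", "theta4"))
    pr[[nm]] <- c(mean = 0, var = 1e4)
  for (nm in c("tauT0sq", "tauT1sq"))
    pr[[nm]] <- c(shape = 0.01, rate = 0.01)
  for (nm in c("tauC0sq", "tauC1sq"))
    pr[[nm]] <- c(shape = 0.001, rate = 0.001)
  pr <- override_prior(pr, list(...), "nn_analysis_prior")
  for (nm in c("mu0", "mu1", "theta1", "theta2", "theta3", "theta4"))
    if (pr[[nm]][2] <= 0)
      stop("nn_analysis_prior: prior variance for '", nm,
           "' must be positive", call. = FALSE)
  for (nm in c("tauT0sq", "tauT1sq", "tauC0sq", "tauC1sq"))
    if (any(pr[[nm]] <= 0))
      stop("nn_analysis_prior: hyperparameters for '", nm,
           "' must be positive", call. = FALSE)
  structure(pr, class = "nn_prior")
}

override_prior <- function(pr, dots, caller) {
  if (!length(dots)) return(pr)
  bad <- setdiff(names(dots), names(pr))
  if (length(bad) || is.null(names(dots)) || any(names(dots) == ""))
    stop(caller, ": unknown parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  for (nm in names(dots)) {
    v <- dots[[nm]]
    if (!is.numeric(v) || length(v) != 2L || any(!is.finite(v)))
      stop(caller, ": override for '", nm,
           "' must be a numeric vector of length 2", call. = FALSE)
    pr[[nm]] <- setNames(as.numeric(v), names(pr[[nm]]))
  }
  pr
}

#' Design (sampling) priors
#'
#' The design prior describes where simulated trials come from at the
#' planning stage. Each model parameter is either `fixed(value)` — the
#' classical power calculation, a zero-variance design prior — or
#' `normal(mean, sd)`, in which case a fresh value is drawn for every
#' simulated replicate and the resulting rejection proportion is the
#' assurance. Draws for positivity-constrained parameters (all ten
#' Weibull-gamma parameters; the normal-normal variances) are truncated at
#' zero by resampling.
#'
#' @param model `"wg"` or `"nn"`.
#' @param ... one descriptor per model parameter (all ten required), each
#'   created by [fixed()] or [rnorm_prior()].
#' @return An object of class `design_prior`.
#' @examples
#' dp <- design_prior_fixed(wg_design_values())       # power mode
#' draw_design_params(dp)                              # always the values
#' @export
design_prior <- function(model = c("wg", "nn"), ...) {
  model <- match.arg(model)
  descr <- list(...)
  expected <- if (model == "wg") {
    c("alpha0", "lambda0", "nu0", "beta0", "gamma0",
      "alpha1", "lambda1", "nu1", "beta1", "gamma1")
  } else {
    c("mu0", "tauT0sq", "theta1", "theta2", "tauC0sq",
      "mu1", "tauT1sq", "theta3", "theta4", "tauC1sq")
  }
  missing <- setdiff(expected, names(descr))
  extra <- setdiff(names(descr), expected)
  if (length(missing) || length(extra))
    stop("design_prior: expected exactly the parameters ",
         paste(expected, collapse = ", "),
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unknown: ",
                                   paste(extra, collapse = ", ")),
         call. = FALSE)
  for (nm in expected)
    if (!inherits(descr[[nm]], "design_descriptor"))
      stop("design_prior: '", nm, "' must be fixed() or rnorm_prior()",
           call. = FALSE)
  structure(list(model = model, descriptors = descr[expected]),
            class = "design_prior")
}

#' @rdname design_prior
#' @param value the fixed parameter value.
#' @export
fixed <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  structure(list(kind = "fixed", value = value), class = "design_descriptor")
}

#' @rdname design_prior
#' @param mean,sd mean and standard deviation of the normal design prior.
#' @export
rnorm_prior <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd), sd > 0)
  structure(list(kind = "normal", mean = mean, sd = sd),
            class = "design_descriptor")
}

#' @rdname design_prior
#' @param params a [wg_params()] or [nn_params()] object whose values become
#'   an all-fixed (power-mode) design prior.
#' @export
design_prior_fixed <- function(params) {
  model <- if (inherits(params, "wg_params")) "wg" else "nn"
  do.call(design_prior,
          c(list(model = model), lapply(unclass(params), fixed)))
}

#' Assurance design priors of the Weibull-gamma fixture
#'
#' Independent normal design priors centered at the fixed design values
#' with the fixture's planning uncertainties: sd 0.1 on the control shape
#' and scale, 0.15 on the control cost shape, 0.05 / 0.2 / 0.2 on the
#' treatment shape, scale and cost shape, and sds 10, 15, 18, 15 on the
#' cost intercepts/slopes. Draws are truncated at zero by resampling.
#'
#' @return A [design_prior()] in assurance mode.
#' @export
wg_assurance_prior <- function() {
  design_prior("wg",
    alpha0 = rnorm_prior(0.75, 0.1), lambda0 = rnorm_prior(0.9, 0.1),
    nu0 = rnorm_prior(1.2, 0.15),
    beta0 = rnorm_prior(50, 10), gamma0 = rnorm_prior(75, 15),
    alpha1 = rnorm_prior(0.5, 0.05), lambda1 = rnorm_prior(1.5, 0.2),
    nu1 = rnorm_prior(3, 0.2),
    beta1 = rnorm_prior(100, 18), gamma1 = rnorm_prior(60, 15))
}

#' Draw one parameter set from a design prior
#'
#' Fixed descriptors return their value; normal descriptors draw once.
#' Positivity-constrained parameters are resampled until positive (budget
#' 1000 per parameter, then an error names the parameter).
#'
#' @param dp a [design_prior()].
#' @return A [wg_params()] or [nn_params()] object.
#' @export
draw_design_params <- function(dp) {
  stopifnot(inherits(dp, "design_prior"))
  positive <- if (dp$model == "wg") names(dp$descriptors)
              else c("tauT0sq", "tauT1sq", "tauC0sq", "tauC1sq")
  vals <- lapply(names(dp$descriptors), function(nm) {
    d <- dp$descriptors[[nm]]
    if (d$kind == "fixed") return(d$value)
    v <- rnorm(1, d$mean, d$sd)
    if (nm %in% positive) {
      tries <- 0L
      while (v <= 0) {
        if (tries >= 1000L)
          stop("draw_design_params: positivity resampling budget exhausted ",
               "for '", nm, "'", call. = FALSE)
        v <- rnorm(1, d$mean, d$sd)
        tries <- tries + 1L
      }
    }
    v
  })
  names(vals) <- names(dp$descriptors)
  if (dp$model == "wg") do.call(wg_params, vals) else do.call(nn_params, vals)
}
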