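#' Run configuration files
#'
#' A run configuration is a YAML document describing one complete design
#' run. Recognised top-level keys (unknown keys are rejected):
#' \describe{
#'   \item{`model`}{`"wg"` or `"nn"`.}
#'   \item{`design_prior`}{map from parameter name to either
#'     `{fixed: value}` or `{normal: [mean, sd]}`; all ten parameters of
#'     the chosen model are required.}
#'   \item{`analysis_prior`}{optional map from parameter name to the two
#'     hyperparameters (gamma shape/rate for the Weibull-gamma model;
#'     normal mean/variance or inverse-gamma shape/rate for the
#'     normal-normal model); omitted entries use the package defaults.}
#'   \item{`censoring`}{map with `kind` and the fields of
#'     [censoring_spec()].}
#'   \item{`grids`}{map with `wtp` and `n_total` vectors.}
#'   \item{`design`}{optional map with `B`, `success_prob`, `target`.}
#'   \item{`mcmc`}{optional map with `chains`, `burn_in`, `keep`, `thin`.}
#'   \item{`seed`}{integer.}
#'   \item{`output`}{optional map with `dir`.}
#' }
#'
#' @param path YAML file path.
#' @param cfg a validated configuration list.
#' @return `read_run_config` returns the validated configuration list;
#'   `write_run_config` writes it and returns `path` invisibly;
#'   `config_to_design_spec` converts it to a [design_spec()].
#' @seealso [preset()] for the shipped example configurations.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  validate_run_config(cfg)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname read_run_config
#' @export
validate_run_config <- function(cfg) {
  allowed <- c("model", "design_prior", "analysis_prior", "censoring",
               "grids", "design", "mcmc", "seed", "output")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop("run config: unknown key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  required <- c("model", "design_prior", "censoring", "grids", "seed")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("run config: missing key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!cfg$model %in% c("wg", "nn"))
    stop("run config: model must be 'wg' or 'nn'", call. = FALSE)
  for (nm in names(cfg$design_prior)) {
    d <- cfg$design_prior[[nm]]
    if (!is.list(d) || length(d) != 1L ||
        !names(d) %in% c("fixed", "normal"))
      stop("run config: design_prior entry '", nm,
           "' must be {fixed: value} or {normal: [mean, sd]}",
           call. = FALSE)
    if (names(d) == "normal" && length(d$normal) != 2L)
      stop("run config: design_prior entry '", nm,
           "' normal needs [mean, sd]", call. = FALSE)
  }
  cens_allowed <- c("kind", "window_lo", "window_hi", "dropout_prob",
                    "dropout_hi", "mean", "sd", "rate")
  bad <- setdiff(names(cfg$censoring), cens_allowed)
  if (length(bad))
    stop("run config: unknown censoring key(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  do.call(censoring_spec, cfg$censoring)        # field validation
  bad <- setdiff(names(cfg$grids), c("wtp", "n_total"))
  if (length(bad) || is.null(cfg$grids$wtp) || is.null(cfg$grids$n_total))
    stop("run config: grids must contain exactly 'wtp' and 'n_total'",
         call. = FALSE)
  if (!is.null(cfg$design)) {
    bad <- setdiff(names(cfg$design), c("B", "success_prob", "target"))
    if (length(bad))
      stop("run config: unknown design key(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(cfg$mcmc)) {
    bad <- setdiff(names(cfg$mcmc), c("chains", "burn_in", "keep", "thin"))
    if (length(bad))
      stop("run config: unknown mcmc key(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(cfg$output)) {
    bad <- setdiff(names(cfg$output), "dir")
    if (length(bad))
      stop("run config: unknown output key(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  config_to_design_spec(cfg)                    # full cross-validation
  cfg
}

#' @rdname read_run_config
#' @export
config_to_design_spec <- function(cfg) {
  descr <- lapply(cfg$design_prior, function(d) {
    if (names(d) == "fixed") fixed(d$fixed)
    else rnorm_prior(d$normal[[1]], d$normal[[2]])
  })
  dp <- do.call(design_prior, c(list(model = cfg$model), descr))
  ap_fun <- if (cfg$model == "wg") wg_analysis_prior else nn_analysis_prior
  ap <- if (is.null(cfg$analysis_prior)) ap_fun()
        else do.call(ap_fun, lapply(cfg$analysis_prior, unlist))
  des <- cfg$design %||% list()
  mc <- cfg$mcmc %||% list()
  design_spec(
    design_prior = dp, analysis_prior = ap,
    censoring = do.call(censoring_spec, cfg$censoring),
    wtp_grid = unlist(cfg$grids$wtp), n_grid = unlist(cfg$grids$n_total),
    B = des$B %||% 300L,
    success_prob = des$success_prob %||% 0.95,
    target = des$target %||% 0.8,
    mcmc = do.call(mcmc_settings,
                   mc[intersect(names(mc),
                                c("chains", "burn_in", "keep", "thin"))]),
    seed = cfg$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shipped example configurations
#'
#' Five ready-made run configurations covering the package's worked
#' examples: `wg_power_3yr` and `wg_power_4yr` (Weibull-gamma power with
#' uniform study-end censoring windows 2.5-3.5 and 3.5-4.5 years),
#' `wg_assurance` (the same trial under normal design priors),
#' `wg_dropout` (the 3-year window with 20% early uniform dropout), and
#' `nn_power` (the normal-normal model, months scale, normal study-end
#' censoring at mean 36 months, sd 2.4).
#'
#' @param name preset name; see `preset_names()`.
#' @return `preset` returns the validated configuration list;
#'   `preset_names` the available names.
#' @export
preset <- function(name) {
  if (!name %in% preset_names())
    stop("unknown preset '", name, "'; available: ",
         paste(preset_names(), collapse = ", "), call. = FALSE)
  read_run_config(system.file("presets", paste0(name, ".yaml"),
                              package = "cedesign", mustWork = TRUE))
}

#' @rdname preset
#' @export
preset_names <- function() {
  sub("\\.yaml$", "",
      list.files(system.file("presets", package = "cedesign"),
                 pattern = "\\.yaml$"))
}
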