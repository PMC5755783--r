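#' Trial data container
#'
#' A validated data frame of observed trial records with columns
#' \describe{
#'   \item{`time`}{observed time, `min(survival, censoring)`, strictly
#'     positive;}
#'   \item{`cost`}{cost accrued by the observed time, strictly positive;}
#'   \item{`arm`}{0 = control, 1 = treatment;}
#'   \item{`event`}{1 if death observed, 0 if the record is right-censored
#'     (in which case `time` is the censoring time and `cost` the accrued —
#'     hence incomplete — cost).}
#' }
#'
#' @param time,cost,arm,event equal-length vectors as described above.
#' @return A `data.frame` of class `trial_data`.
#' @seealso [simulate_trial()], [read_trial()], [write_trial()]
#' @export
trial_data <- function(time, cost, arm, event) {
  n <- length(time)
  if (length(cost) != n || length(arm) != n || length(event) != n)
    stop("trial_data: all columns must have the same length", call. = FALSE)
  if (n > 0 && (any(!is.finite(time)) || any(time <= 0)))
    stop("trial_data: 'time' must be finite and strictly positive",
         call. = FALSE)
  if (n > 0 && (any(!is.finite(cost)) || any(cost <= 0)))
    stop("trial_data: 'cost' must be finite and strictly positive",
         call. = FALSE)
  arm <- check_arm(arm)
  if (n > 0 && !all(event %in% c(0, 1)))
    stop("trial_data: 'event' must be 0 or 1", call. = FALSE)
  structure(data.frame(time = as.numeric(time), cost = as.numeric(cost),
                       arm = arm, event = as.integer(event)),
            class = c("trial_data", "data.frame"))
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("trial_data: %d records (%d control / %d treatment), %.1f%% censored\n",
              nrow(x), sum(x$arm == 0L), sum(x$arm == 1L),
              100 * mean(x$event == 0L)))
  NextMethod()
}

#' Read / write trial data as CSV
#'
#' The on-disk format is a plain CSV with header `time,cost,arm,event` and
#' no row names; `event` is 1 for an observed death, 0 for censoring. This
#' is both the output format of the simulators and the accepted input
#' format for user-supplied datasets passed to [fit_trial()].
#'
#' @param path file path.
#' @param data a [trial_data()] object (for `write_trial`).
#' @return `read_trial` returns a [trial_data()]; `write_trial` returns
#'   `path` invisibly.
#' @export
read_trial <- function(path) {
  df <- read.csv(path)
  required <- c("time", "cost", "arm", "event")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("trial CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  trial_data(df$time, df$cost, df$arm, df$event)
}

#' @rdname read_trial
#' @export
write_trial <- function(data, path) {
  stopifnot(inherits(data, "trial_data"))
  write.csv(as.data.frame(data)[c("time", "cost", "arm", "event")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
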