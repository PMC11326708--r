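# Pixel <-> hour <-> millimetre calibration from time marks, and the
# growth-rate calculation. Growth of the colony is close to, but not
# exactly, linear; the default calibration is therefore the mean of the
# per-interval rates between consecutive marks rather than a global fit.

#' Fit the pixel-to-hour calibration from time marks
#'
#' The growth rate in px/h is the mean over consecutive mark pairs of
#' delta-x / delta-t (`method = "interval_mean"`, the default), or the
#' slope of a least-squares fit of x on t (`method = "least_squares"`).
#'
#' @param marks a `time_mark_set` with times attached.
#' @param method `"interval_mean"` or `"least_squares"`.
#' @return a `calibration_model`: list with `px_per_hour`,
#'   `hours_per_px`, `mm_per_px` (NULL until a physical measurement is
#'   supplied), `marks`, `method`.
#' @export
fit_time_calibration <- function(marks, method = c("interval_mean",
                                                   "least_squares")) {
  method <- match.arg(method)
  stopifnot(inherits(marks, "time_mark_set"))
  x <- marks$x_positions; t <- marks$times_h
  if (is.null(t))
    rt_error("marks carry no times; call set_mark_times() first",
             "rt_calibration_error")
  if (length(x) < 2)
    rt_error("at least 2 time marks are needed for calibration",
             "rt_calibration_error")
  dx <- diff(x); dt <- diff(t)
  if (any(dx <= 0) || any(dt <= 0))
    rt_error("mark positions and times must both be strictly increasing",
             "rt_ordering_error")
  px_per_hour <- if (method == "interval_mean") mean(dx / dt) else
    unname(coef(lm(x ~ t))[2])
  structure(list(px_per_hour = px_per_hour,
                 hours_per_px = 1 / px_per_hour,
                 mm_per_px = NULL, marks = marks, method = method),
            class = "calibration_model")
}

#' Growth rate in millimetres per hour
#'
#' The user-measured physical distance between the first and last time
#' marks fixes the mm-per-px scale; the rate is the calibrated px/h
#' growth times that scale. Without a measurement the rate is not
#' determinable and `NA` is returned (reported as "N/A" downstream).
#'
#' @param marks a `time_mark_set` with times.
#' @param measured_mm physical distance (mm) between the first and last
#'   marks, or `NULL`.
#' @param method passed to [fit_time_calibration()].
#' @return growth rate in mm/h, or `NA_real_` when no measurement given.
#' @export
growth_rate <- function(marks, measured_mm = NULL,
                        method = c("interval_mean", "least_squares")) {
  if (is.null(measured_mm) || (length(measured_mm) == 1 && is.na(measured_mm)))
    return(NA_real_)
  if (measured_mm <= 0)
    rt_error("measured distance must be positive", "rt_input_error")
  cal <- fit_time_calibration(marks, method = match.arg(method))
  x <- marks$x_positions
  mm_per_px <- measured_mm / (x[length(x)] - x[1])
  cal$px_per_hour * mm_per_px
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("calibration_model (%s): %.4f px/h (%.5f h/px), %d marks\n",
              x$method, x$px_per_hour, x$hours_per_px,
              length(x$marks$x_positions)))
  invisible(x)
}
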