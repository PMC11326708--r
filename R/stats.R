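# Summary statistics over user-selected sets of period estimates.

#' Summarize a selection of period estimates
#'
#' Mean, standard deviation and standard error of the mean for a set of
#' periods from a single estimation method. The SD uses the sample
#' convention (n - 1 denominator) since the selected tubes are a sample;
#' a single estimate yields SD = SEM = 0. Set `population = TRUE` for
#' the n-denominator SD.
#'
#' @param periods either a numeric vector of periods (hours) with
#'   `method` given, or a data.frame with `method` and `period_h`
#'   columns (e.g. rows collected from [all_periods()]).
#' @param method the estimator name (required for numeric input; for
#'   data.frame input all rows must share one method).
#' @param population use the population SD convention.
#' @return a `period_summary`: list with `n`, `mean_h`, `sd_h`, `sem_h`,
#'   `method`.
#' @export
summarize_periods <- function(periods, method = NULL, population = FALSE) {
  if (is.data.frame(periods)) {
    if (!all(c("method", "period_h") %in% names(periods)))
      rt_error("data.frame input needs 'method' and 'period_h' columns",
               "rt_selection_error")
    um <- unique(periods$method)
    if (length(um) > 1)
      rt_error("selection mixes estimates from different methods",
               "rt_selection_error")
    method <- um
    periods <- periods$period_h
  }
  periods <- periods[!is.na(periods)]
  n <- length(periods)
  if (n < 1)
    rt_error("empty selection", "rt_selection_error")
  m <- mean(periods)
  s <- if (population) sqrt(mean((periods - m)^2))
       else if (n == 1) 0 else sd(periods)
  structure(list(n = n, mean_h = m, sd_h = s, sem_h = s / sqrt(n),
                 method = method %||% NA_character_),
            class = "period_summary")
}

#' @export
print.period_summary <- function(x, ...) {
  cat(sprintf("period_summary (%s): n = %d, mean = %.3f h, SD = %.3f h, SEM = %.3f h\n",
              x$method, x$n, x$mean_h, x$sd_h, x$sem_h))
  invisible(x)
}
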