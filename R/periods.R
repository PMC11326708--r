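# Circadian period estimation.
#
# Four estimators run on the interpolated densitometry of a tube (or a
# window of it bounded by two time marks):
#   * linear regression: mean conidial band spacing times hours-per-px;
#   * Sokolove-Bushell chi-squared periodogram: fold the series at each
#     candidate period P into K = floor(N/P) complete rows and score
#       Q_P = K * sum_h (Xbar_h - Xbar)^2 / [ (1/(N-1)) sum_i (X_i - Xbar)^2 ]
#     where Xbar_h is the mean of the K values at fold position h;
#   * Lomb-Scargle periodogram: for a mean-centred series X_j at times t_j,
#       P(f) = 1/2 * [ (sum X_j cos w(t_j - tau))^2 / sum cos^2 w(t_j - tau)
#                    + (sum X_j sin w(t_j - tau))^2 / sum sin^2 w(t_j - tau) ]
#     with w = 2 pi f and tan(2 w tau) = sum sin(2 w t_j) / sum cos(2 w t_j);
#   * continuous wavelet transform: complex Morlet, log-spaced scales across
#     the search band; the per-time ridge of maximal amplitude is averaged
#     over the points exceeding 75% of the global maximum.
#
# The spectrum peak is always taken within a circadian search band
# (default 14-40 h): an unrestricted argmax can land on harmonics or the
# slow growth-front trend rather than the circadian component.

RT_BAND_H <- c(14, 40)

profile_values <- function(p) {
  if (inherits(p, "densitometry_profile")) p$values else as.numeric(p)
}

# A series is degenerate when its variation is at numerical-noise level
# relative to its magnitude (smoothing a constant leaves ~1e-14 jitter).
is_degenerate_series <- function(v) {
  sd(v) <= 1e-8 * max(1, abs(mean(v)))
}

#' Restrict a profile and its marks to the span between two marks
#'
#' Period analyses can be run on the region between any two marked time
#' points; this slices the profile columns to `[x_i, x_j]` (inclusive)
#' and keeps only the marks inside.
#'
#' @param p a `densitometry_profile`.
#' @param marks a `time_mark_set` with times.
#' @param i,j mark indices, `1 <= i < j <=` number of marks.
#' @return list with elements `profile` (x_offset set so positions stay
#'   in the original frame) and `marks`.
#' @export
slice_window <- function(p, marks, i, j) {
  stopifnot(inherits(p, "densitometry_profile"),
            inherits(marks, "time_mark_set"))
  nm <- length(marks$x_positions)
  if (!(i >= 1 && i < j && j <= nm))
    rt_error(sprintf("invalid mark window [%s, %s] for %d marks", i, j, nm),
             "rt_window_error")
  xi <- round(marks$x_positions[i]); xj <- round(marks$x_positions[j])
  lo <- xi - p$x_offset; hi <- xj - p$x_offset
  sub <- new_profile(p$values[lo:hi], p$variant, p$tube_index,
                     x_offset = xi - 1L)
  keep <- marks$x_positions >= xi & marks$x_positions <= xj
  sm <- new_time_marks(marks$x_positions[keep],
                       if (!is.null(marks$times_h)) marks$times_h[keep])
  list(profile = sub, marks = sm)
}

new_period_estimate <- function(method, period_h, details = list()) {
  structure(list(method = method, period_h = period_h, details = details),
            class = "period_estimate")
}

#' Linear-regression period from band spacing
#'
#' The period is the mean spacing between consecutive conidial band
#' peaks (px) converted to hours with the calibrated growth rate.
#'
#' @param bands a `band_peak_set` with at least two peaks.
#' @param cal a `calibration_model`.
#' @return a `period_estimate` (`method = "linear_regression"`).
#' @export
period_linear_regression <- function(bands, cal) {
  stopifnot(inherits(bands, "band_peak_set"),
            inherits(cal, "calibration_model"))
  x <- bands$x_positions
  if (length(x) < 2)
    rt_error("at least 2 band peaks are needed for the linear-regression period",
             "rt_insufficient_peaks")
  spacing <- mean(diff(x))
  new_period_estimate("linear_regression", spacing * cal$hours_per_px,
                      list(n_peaks = length(x), mean_spacing_px = spacing))
}

new_periodogram <- function(periods_h, power, method, peak_period_h) {
  structure(list(periods_h = periods_h, power = power, method = method,
                 peak_period_h = peak_period_h),
            class = "rt_periodogram")
}

#' Sokolove-Bushell chi-squared periodogram
#'
#' For each integer candidate period P (px) inside the search band, the
#' series is folded into K = floor(N/P) complete rows (trailing remainder
#' discarded) and scored with the chi-squared statistic
#' `Q_P = K * sum_h (Xbar_h - Xbar)^2 / [(1/(N-1)) * sum_i (X_i - Xbar)^2]`,
#' N being the folded length K*P. The peak is the argmax within the band.
#'
#' @param p a `densitometry_profile` or numeric vector (px sampling).
#' @param cal a `calibration_model` (for px to hour conversion).
#' @param band_h circadian search band in hours, `c(low, high)`.
#' @return an `rt_periodogram` with `periods_h`, `power`,
#'   `peak_period_h`.
#' @export
periodogram_sokolove_bushell <- function(p, cal, band_h = RT_BAND_H) {
  v <- profile_values(p)
  if (is_degenerate_series(v))
    rt_error("series has zero variance; periodogram undefined",
             "rt_degenerate_series")
  hpp <- cal$hours_per_px
  P_lo <- max(2L, as.integer(ceiling(band_h[1] / hpp)))
  P_hi <- min(as.integer(floor(band_h[2] / hpp)), length(v) %/% 2L)
  if (P_hi < P_lo)
    rt_error("series too short for the requested period band",
             "rt_window_error")
  Ps <- P_lo:P_hi
  Q <- vapply(Ps, function(P) {
    K <- length(v) %/% P
    X <- v[seq_len(K * P)]
    N <- K * P
    Xbar <- mean(X)
    Xh <- rowMeans(matrix(X, nrow = P))       # mean at each fold position
    denom <- sum((X - Xbar)^2) / (N - 1)
    K * sum((Xh - Xbar)^2) / denom
  }, numeric(1))
  k <- which.max(Q)
  new_periodogram(Ps * hpp, Q, "sokolove_bushell", Ps[k] * hpp)
}

#' Lomb-Scargle periodogram
#'
#' Evaluates the classical least-squares spectral power of the
#' mean-centred series on a frequency grid spanning the search band with
#' oversampling, using the phase offset tau defined by
#' `tan(2 w tau) = sum(sin 2 w t_j) / sum(cos 2 w t_j)` that makes the
#' sine and cosine components orthogonal.
#'
#' @inheritParams periodogram_sokolove_bushell
#' @param oversample frequency-grid oversampling factor (grid step
#'   `1 / (oversample * N)` cycles per sample).
#' @return an `rt_periodogram`.
#' @export
periodogram_lomb_scargle <- function(p, cal, band_h = RT_BAND_H,
                                     oversample = 16) {
  v <- profile_values(p)
  n <- length(v)
  if (n < 8)
    rt_error("at least 8 samples are required", "rt_window_error")
  if (is_degenerate_series(v))
    rt_error("series has zero variance; periodogram undefined",
             "rt_degenerate_series")
  x <- v - mean(v)
  hpp <- cal$hours_per_px
  tt <- seq_len(n) - 1
  f_lo <- 1 / (band_h[2] / hpp)
  f_hi <- 1 / (max(band_h[1] / hpp, 2))       # Nyquist guard
  fs <- seq(f_lo, f_hi, by = 1 / (oversample * n))
  pow <- vapply(fs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * tt)), sum(cos(2 * w * tt))) / (2 * w)
    ct <- cos(w * (tt - tau)); st <- sin(w * (tt - tau))
    0.5 * (sum(x * ct)^2 / sum(ct^2) + sum(x * st)^2 / sum(st^2))
  }, numeric(1))
  k <- which.max(pow)
  new_periodogram((1 / fs) * hpp, pow, "lomb_scargle", (1 / fs[k]) * hpp)
}

#' Continuous wavelet transform period and drift
#'
#' Convolves the (mean-centred, optionally linearly detrended) series
#' with complex Morlet wavelets at log-spaced scales spanning the search
#' band. For each time point the ridge is the period of maximal
#' amplitude; ridge points whose amplitude exceeds 75% of the global
#' maximum are accepted. The tube's period is the arithmetic mean of the
#' accepted ridge periods; the slope (hours of period per hour of
#' elapsed time, a measure of period drift) is the least-squares line
#' through the accepted (time, ridge period) points.
#'
#' @inheritParams periodogram_sokolove_bushell
#' @param n_scales number of log-spaced scales across the band.
#' @param center_freq Morlet centre frequency (cycles per unit scale).
#' @param bandwidth Morlet Gaussian bandwidth parameter.
#' @param detrend remove a linear trend before transforming (the
#'   growth-front brightness gradient induces a trend; default on).
#' @param accept_frac ridge acceptance threshold as a fraction of the
#'   global maximum amplitude.
#' @return a `cwt_result`: `amplitude` (time x period matrix),
#'   `times_h`, `periods_h`, `ridge` (data.frame), `period_h`, `slope`.
#' @export
cwt_analysis <- function(p, cal, band_h = RT_BAND_H, n_scales = 100,
                         center_freq = 1.0, bandwidth = 1.5,
                         detrend = TRUE, accept_frac = 0.75) {
  v <- profile_values(p)
  n <- length(v)
  if (is_degenerate_series(v))
    rt_error("series has zero variance; transform undefined",
             "rt_degenerate_series")
  x <- v - mean(v)
  if (detrend) x <- unname(lm(x ~ seq_len(n))$residuals)
  hpp <- cal$hours_per_px
  periods_px <- exp(seq(log(band_h[1] / hpp), log(band_h[2] / hpp),
                        length.out = n_scales))
  if (n < 4 * min(periods_px))
    rt_error("series too short for the requested period band",
             "rt_window_error")
  scales <- periods_px * center_freq
  tsup <- 5                                  # Gaussian support in wavelet time
  Lmax <- ceiling(tsup * max(scales))
  N2 <- nextn(n + 2 * Lmax + 1, 2)
  fx <- fft(c(x, rep(0, N2 - n)))
  amp <- matrix(0, n, n_scales)
  norm <- (pi * bandwidth)^(-0.25)
  for (si in seq_len(n_scales)) {
    a <- scales[si]
    L <- ceiling(tsup * a)
    t_w <- (-L:L) / a
    # L1 normalization (1/a): sinusoids of equal amplitude get equal ridge
    # amplitude at every scale, so the ridge argmax is unbiased in scale
    psi <- norm * exp(2i * pi * center_freq * t_w) * exp(-t_w^2 / bandwidth)
    kern <- rev(Conj(psi)) / a
    fk <- fft(c(kern, rep(0, N2 - length(kern))))
    conv <- fft(fx * fk, inverse = TRUE) / N2
    amp[, si] <- Mod(conv[seq_len(n) + L])
  }
  periods_h <- periods_px * hpp
  times_h <- (seq_len(n) - 1) * hpp
  ridge_idx <- max.col(amp, ties.method = "first")
  ridge_amp <- amp[cbind(seq_len(n), ridge_idx)]
  accepted <- ridge_amp > accept_frac * max(amp)
  ridge <- data.frame(time_h = times_h, period_h = periods_h[ridge_idx],
                      amplitude = ridge_amp, accepted = accepted)
  period_h <- mean(ridge$period_h[accepted])
  slope <- if (sum(accepted) < 2) {
    warning("fewer than 2 accepted ridge points; slope reported as 0")
    0
  } else {
    unname(coef(lm(period_h ~ time_h, data = ridge[accepted, ]))[2])
  }
  structure(list(amplitude = amp, times_h = times_h, periods_h = periods_h,
                 ridge = ridge, period_h = period_h, slope = slope),
            class = "cwt_result")
}

#' @export
print.rt_periodogram <- function(x, ...) {
  cat(sprintf("%s periodogram: %d candidate periods in [%.2f, %.2f] h, peak at %.3f h\n",
              x$method, length(x$periods_h), min(x$periods_h),
              max(x$periods_h), x$peak_period_h))
  invisible(x)
}

#' @export
print.cwt_result <- function(x, ...) {
  cat(sprintf("cwt_result: %d x %d amplitude matrix, period %.3f h, slope %.4f h/h (%d accepted ridge points)\n",
              nrow(x$amplitude), ncol(x$amplitude), x$period_h, x$slope,
              sum(x$ridge$accepted)))
  invisible(x)
}

#' @export
print.period_estimate <- function(x, ...) {
  cat(sprintf("period_estimate: %s, %.3f h\n", x$method, x$period_h))
  invisible(x)
}

#' All four period estimates for an analyzed tube
#'
#' Runs linear regression, Sokolove-Bushell, Lomb-Scargle and CWT on the
#' same (optionally windowed) interpolated densitometry. Estimators fail
#' independently: a failed method yields `NA` with its error message
#' rather than aborting the others.
#'
#' @param record a `tube_record` from [analyze_pack()].
#' @param window `NULL` for the full trace, or `c(i, j)` mark indices
#'   passed to [slice_window()].
#' @param band_h circadian search band in hours.
#' @param ... passed on to the spectral estimators.
#' @return data.frame with columns `method`, `period_h`, `error`
#'   (NA when the method succeeded), plus attributes `window`.
#' @export
all_periods <- function(record, window = NULL, band_h = RT_BAND_H, ...) {
  stopifnot(inherits(record, "tube_record"))
  pr <- record_profiles(record)
  marks <- record_marks(record)
  prof <- pr$interpolated
  if (!is.null(window)) {
    sl <- slice_window(prof, marks, window[1], window[2])
    prof <- sl$profile; marks <- sl$marks
  }
  cal <- fit_time_calibration(marks)
  xr <- c(prof$x_offset + 1, prof$x_offset + length(prof$values))
  bands <- record$band_x[record$band_x >= xr[1] & record$band_x <= xr[2]]
  run <- function(fn) {
    tryCatch(list(value = fn(), error = NA_character_),
             racetube_error = function(e) list(value = NA_real_,
                                               error = conditionMessage(e)))
  }
  lr <- run(function() period_linear_regression(new_band_peaks(bands), cal)$period_h)
  sb <- run(function() periodogram_sokolove_bushell(prof, cal, band_h)$peak_period_h)
  ls <- run(function() periodogram_lomb_scargle(prof, cal, band_h, ...)$peak_period_h)
  cw <- run(function() cwt_analysis(prof, cal, band_h)$period_h)
  out <- data.frame(
    method = c("linear_regression", "sokolove_bushell", "lomb_scargle", "cwt"),
    period_h = c(lr$value, sb$value, ls$value, cw$value),
    error = c(lr$error, sb$error, ls$error, cw$error),
    stringsAsFactors = FALSE)
  attr(out, "window") <- window %||% c(1L, length(record$mark_x))
  out
}
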