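# Per-tube densitometry: column-mean brightness traces, Savitzky-Golay
# smoothing, time-mark excision, and conidial band-peak detection.
#
# Two smoothing passes serve different features. A 4th-order filter over a
# wide window suppresses mycelial texture while keeping the broad conidial
# bands; an 8th-order filter over a 31 px window preserves the sharp, deep
# notches left by the daily pen marks so they can be located precisely.

RT_BAND_SG_WINDOW <- 45   # px; about half a band at typical scale
RT_BAND_SG_ORDER <- 4
RT_MARK_SG_WINDOW <- 31   # px; nominal 30, rounded up to the odd size the
RT_MARK_SG_ORDER <- 8     # filter requires
RT_MARK_PROMINENCE <- 15  # brightness units
RT_MARK_MIN_SLOPE <- 3    # brightness units per px on the steepest flank
RT_MARK_SLOPE_WINDOW <- 5 # px examined on each side of a candidate mark
RT_MARK_MIN_DISTANCE <- 25 # px; deeper minima suppress shallower
                           # neighbours (the order-8 filter rings out to
                           # ~21 px around a pen-mark notch)
RT_MARK_HALF_WIDTH <- 12  # px excised on each side of a mark
RT_MARK_EDGE_MARGIN <- 15 # px at each profile end where the smoothing
                          # filter extrapolates and minima are artifacts
RT_BAND_MIN_WIDTH <- 10   # px at half prominence
# Band prominence sits above the residual ripple that the smoothing
# filters leave around excised pen marks (~9-13 units) and well below the
# prominence of genuine bands at usable contrast (>= ~35 units).
RT_BAND_PROMINENCE <- 15  # brightness units
RT_BAND_EDGE_MARGIN <- 30 # px; a maximum this close to a profile end has
                          # no complete flank and cannot be verified as a
                          # band (edge fits + excision bridges also
                          # interact to create maxima there)
RT_BAND_MIN_DISTANCE <- 30 # px; bands are never closer than this
RT_PROFILE_INSET <- 3     # px kept clear of each boundary line

new_profile <- function(values, variant, tube_index, x_offset = 0L) {
  structure(list(values = as.numeric(values), variant = variant,
                 tube_index = as.integer(tube_index),
                 x_offset = as.integer(x_offset)),
            class = "densitometry_profile")
}

#' Raw densitometry of one tube region
#'
#' For every image column, the mean brightness of the pixels between the
#' tube's two (possibly sloped) boundary lines, inset by a margin so the
#' dark boundary pixels themselves are excluded.
#'
#' @param img a `race_tube_image`.
#' @param boundaries a `tube_boundary_set` from [detect_tube_boundaries()].
#' @param tube_index which tube (1 = topmost).
#' @param inset rows kept clear of each detected boundary line (no inset
#'   is applied at the image's own edges).
#' @return a `densitometry_profile` (variant `"raw"`): `values` of length
#'   1160 in \[0, 255\].
#' @export
tube_densitometry <- function(img, boundaries, tube_index,
                              inset = RT_PROFILE_INSET) {
  stopifnot(inherits(img, "race_tube_image"),
            inherits(boundaries, "tube_boundary_set"))
  tb <- boundaries$tubes
  if (!tube_index %in% tb$index)
    rt_error(sprintf("no tube with index %d", tube_index), "rt_no_tubes_error")
  t_ <- tb[tb$index == tube_index, ]
  px <- img$pixels
  nc <- ncol(px); nr <- nrow(px)
  xs <- seq_len(nc)
  frac <- (xs - 1) / (nc - 1)
  ytop <- t_$top_left + (t_$top_right - t_$top_left) * frac        # 1-based
  ybot <- t_$bottom_left + (t_$bottom_right - t_$bottom_left) * frac
  in_top <- if (t_$top_method == "edge") 0 else inset
  in_bot <- if (t_$bottom_method == "edge") 0 else inset
  r0 <- pmin(pmax(floor(ytop) + 1 + in_top, 1), nr)
  r1 <- pmin(pmax(ceiling(ybot) - 1 - in_bot, 1), nr)
  r1 <- pmax(r1, r0)
  vals <- vapply(xs, function(x) mean(px[r0[x]:r1[x], x]), numeric(1))
  new_profile(vals, "raw", tube_index)
}

sg_smooth <- function(p, window, order, variant) {
  stopifnot(inherits(p, "densitometry_profile"))
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L   # filter needs odd windows
  if (window <= order)
    rt_error("smoothing window must exceed the polynomial order",
             "rt_config_error")
  v <- signal::sgolayfilt(p$values, p = order, n = window)
  v <- pmin(pmax(v, 0), 255)
  new_profile(v, variant, p$tube_index, p$x_offset)
}

#' Smooth a raw profile for band detection
#'
#' Savitzky-Golay least-squares polynomial smoothing, order 4, over a
#' wide window (default 45 px): strong enough to flatten pixel texture,
#' gentle enough to keep conidial band peaks.
#'
#' @param p raw `densitometry_profile`.
#' @param window window length in px (rounded up to odd).
#' @param order polynomial order.
#' @return profile with variant `"band_smoothed"`.
#' @export
smooth_for_bands <- function(p, window = RT_BAND_SG_WINDOW,
                             order = RT_BAND_SG_ORDER) {
  sg_smooth(p, window, order, "band_smoothed")
}

#' Smooth a raw profile for time-mark detection
#'
#' Savitzky-Golay smoothing, order 8 over a 31 px window (the nominal
#' 30 px rounded up to the odd length the filter requires). The high
#' order preserves the sharp pen-mark notches.
#'
#' @inheritParams smooth_for_bands
#' @return profile with variant `"mark_smoothed"`.
#' @export
smooth_for_marks <- function(p, window = RT_MARK_SG_WINDOW,
                             order = RT_MARK_SG_ORDER) {
  sg_smooth(p, window, order, "mark_smoothed")
}

new_time_marks <- function(x_positions, times_h = NULL) {
  x <- as.numeric(x_positions)
  if (is.unsorted(x, strictly = TRUE))
    rt_error("mark x positions must be strictly increasing",
             "rt_ordering_error")
  if (!is.null(times_h)) {
    times_h <- as.numeric(times_h)
    if (length(times_h) != length(x))
      rt_error("mark times and positions differ in length",
               "rt_calibration_error")
    if (is.unsorted(times_h, strictly = TRUE))
      rt_error("mark times must be strictly increasing", "rt_ordering_error")
  }
  structure(list(x_positions = x, times_h = times_h), class = "time_mark_set")
}

#' Detect time-mark pen artifacts in a smoothed profile
#'
#' Pen marks appear as extreme local minima. A minimum is accepted when it
#' satisfies both criteria: topographic prominence at least
#' `prominence`, and a steep flank - the largest one-sample drop within
#' `slope_window` px on either side at least `min_slope`. The slope
#' criterion rejects the broad, gentle troughs between conidial bands.
#' Finally, when two accepted minima fall within `min_distance` px the
#' deeper one wins: the high-order smoothing filter rings around a deep
#' narrow notch, and the flanking ripple minima would otherwise register
#' as marks (real daily marks are never this close together).
#'
#' @param p a `densitometry_profile`, normally variant `"mark_smoothed"`.
#' @param prominence minimum trough prominence, brightness units.
#' @param min_slope minimum steepest flank slope, brightness units / px.
#' @param slope_window px examined on each side of a candidate.
#' @param min_distance suppression radius between accepted marks, px.
#' @param edge_margin px at each end of the profile where detections are
#'   discarded (the smoothing filter extrapolates there and its endpoint
#'   fits produce artifact minima).
#' @param add,remove numeric vectors of x positions (px) of marks to force
#'   in or take out after detection; `remove` drops the nearest detected
#'   mark within 10 px.
#' @return a `time_mark_set` with `x_positions` (no times yet); see
#'   [set_mark_times()].
#' @export
detect_time_marks <- function(p, prominence = RT_MARK_PROMINENCE,
                              min_slope = RT_MARK_MIN_SLOPE,
                              slope_window = RT_MARK_SLOPE_WINDOW,
                              min_distance = RT_MARK_MIN_DISTANCE,
                              edge_margin = RT_MARK_EDGE_MARGIN,
                              add = NULL, remove = NULL) {
  stopifnot(inherits(p, "densitometry_profile"))
  v <- p$values
  n <- length(v)
  tr <- find_troughs(v, min_prominence = prominence)
  tr <- tr[tr$index > edge_margin & tr$index <= n - edge_margin, ,
           drop = FALSE]
  keep <- vapply(tr$index, function(i) {
    lo <- max(1L, i - slope_window); hi <- min(n, i + slope_window)
    sl <- if (i > lo) max(abs(diff(v[lo:i]))) else 0
    sr <- if (hi > i) max(abs(diff(v[i:hi]))) else 0
    max(sl, sr) >= min_slope
  }, logical(1))
  cand <- tr[keep, , drop = FALSE]
  # deepest-first suppression of close neighbours (filter ringing)
  x <- numeric(0)
  for (i in cand$index[order(cand$height)]) {
    if (!length(x) || all(abs(x - i) >= min_distance)) x <- c(x, i)
  }
  x <- sort(x)
  if (length(remove)) {
    for (r in remove) {
      d <- abs(x - r)
      if (length(d) && min(d) <= 10) x <- x[-which.min(d)]
    }
  }
  if (length(add)) x <- sort(unique(c(x, round(add))))
  new_time_marks(x)
}

#' Attach clock times to detected marks
#'
#' Times are the user's record of when each pen mark was made, in hours
#' since transfer to constant darkness. Either give the full vector or a
#' fixed `interval` (hours) to assign 0, interval, 2*interval, ...
#'
#' @param marks a `time_mark_set`.
#' @param times numeric vector of hours, one per mark.
#' @param interval fixed spacing in hours (used when `times` is `NULL`).
#' @return the `time_mark_set` with `times_h` filled in.
#' @export
set_mark_times <- function(marks, times = NULL, interval = NULL) {
  stopifnot(inherits(marks, "time_mark_set"))
  n <- length(marks$x_positions)
  if (is.null(times)) {
    if (is.null(interval))
      rt_error("either explicit times or an interval is required",
               "rt_calibration_error")
    times <- interval * (seq_len(n) - 1)
  }
  new_time_marks(marks$x_positions, times)
}

#' Excise time-mark artifacts by linear interpolation
#'
#' For each mark at x, values in the window \[x - w, x + w\] are replaced
#' by the straight line joining the profile values just outside the
#' window. Overlapping windows are merged; windows clipped by a profile
#' end are held constant at the surviving anchor. Values outside every
#' window are untouched.
#'
#' @param p a `densitometry_profile`, normally variant `"band_smoothed"`.
#' @param marks a `time_mark_set` (positions in the profile's x frame).
#' @param half_width w, the excision half-width in px.
#' @return profile with variant `"interpolated"`.
#' @export
interpolate_over_marks <- function(p, marks, half_width = RT_MARK_HALF_WIDTH) {
  stopifnot(inherits(p, "densitometry_profile"),
            inherits(marks, "time_mark_set"))
  v <- p$values
  n <- length(v)
  xs <- marks$x_positions - p$x_offset
  xs <- xs[xs >= 1 & xs <= n]
  if (!length(xs)) return(new_profile(v, "interpolated", p$tube_index, p$x_offset))
  lo <- pmax(round(xs) - half_width, 1)
  hi <- pmin(round(xs) + half_width, n)
  # merge overlapping windows
  ord <- order(lo)
  lo <- lo[ord]; hi <- hi[ord]
  ml <- lo[1]; mh <- hi[1]; wins <- list()
  for (k in seq_along(lo)[-1]) {
    if (lo[k] <= mh + 1) mh <- max(mh, hi[k])
    else { wins[[length(wins) + 1]] <- c(ml, mh); ml <- lo[k]; mh <- hi[k] }
  }
  wins[[length(wins) + 1]] <- c(ml, mh)
  for (w in wins) {
    a <- w[1] - 1; b <- w[2] + 1
    if (a < 1 && b > n) next                      # window covers everything
    if (a < 1) { v[w[1]:w[2]] <- v[b]; next }     # one-sided hold
    if (b > n) { v[w[1]:w[2]] <- v[a]; next }
    idx <- w[1]:w[2]
    v[idx] <- v[a] + (v[b] - v[a]) * (idx - a) / (b - a)
  }
  new_profile(v, "interpolated", p$tube_index, p$x_offset)
}

new_band_peaks <- function(x_positions) {
  x <- as.numeric(x_positions)
  if (is.unsorted(x, strictly = TRUE))
    rt_error("band peak positions must be strictly increasing",
             "rt_ordering_error")
  structure(list(x_positions = x), class = "band_peak_set")
}

#' Detect conidial band peaks
#'
#' Local maxima of the interpolated profile with sufficient width (at
#' half prominence) and prominence are taken as the centres of maximal
#' conidial banding. The width criterion rejects narrow noise spikes;
#' when two accepted maxima fall within `min_distance` px the more
#' prominent one wins, suppressing shoulder ripples from smoothing,
#' resampling, or mark excision (bands are never closer than roughly
#' half a circadian cycle).
#'
#' @param p a `densitometry_profile`, normally variant `"interpolated"`.
#' @param min_width minimum width at half prominence, px.
#' @param prominence minimum prominence, brightness units.
#' @param min_distance suppression radius between accepted peaks, px.
#' @param edge_margin px at each profile end where maxima are discarded.
#' @param add,remove position overrides as in [detect_time_marks()].
#' @return a `band_peak_set` with strictly increasing `x_positions`
#'   (in the profile's x frame).
#' @export
detect_band_peaks <- function(p, min_width = RT_BAND_MIN_WIDTH,
                              prominence = RT_BAND_PROMINENCE,
                              min_distance = RT_BAND_MIN_DISTANCE,
                              edge_margin = RT_BAND_EDGE_MARGIN,
                              add = NULL, remove = NULL) {
  stopifnot(inherits(p, "densitometry_profile"))
  pk <- find_peaks(p$values, min_prominence = prominence,
                   min_width = min_width)
  pk <- pk[pk$index > edge_margin &
             pk$index <= length(p$values) - edge_margin, , drop = FALSE]
  keep <- numeric(0)
  for (k in order(-pk$prominence)) {
    if (!length(keep) || all(abs(pk$index[keep] - pk$index[k]) >= min_distance))
      keep <- c(keep, k)
  }
  pk <- pk[sort(keep), , drop = FALSE]
  x <- pk$index + p$x_offset
  if (length(remove)) {
    for (r in remove) {
      d <- abs(x - r)
      if (length(d) && min(d) <= 10) x <- x[-which.min(d)]
    }
  }
  if (length(add)) x <- sort(unique(c(x, round(add))))
  new_band_peaks(x)
}

#' @export
print.densitometry_profile <- function(x, ...) {
  cat(sprintf("densitometry_profile: tube %d, variant %s, %d columns, range [%.1f, %.1f]\n",
              x$tube_index, x$variant, length(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}
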