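# End-to-end analysis of a pack image into per-tube records.
#
# A tube record stores only primary features (boundaries, mark and band
# positions, mark times, growth rate, raw densitometry). Period estimates
# are always recomputed from these on demand, so later edits to marks or
# peaks can never desynchronize stored periods.

new_tube_record <- function(pack_name, tube_index, source_image,
                            greyscale_image_ref, tube_y_bounds, mark_x,
                            mark_times_h, band_x, growth_rate_mm_per_h,
                            raw_densitometry) {
  structure(list(
    pack_name = pack_name,
    tube_index = as.integer(tube_index),
    source_image = source_image,
    greyscale_image_ref = greyscale_image_ref,
    tube_y_bounds = tube_y_bounds,        # data.frame: top and bottom lines
    mark_x = as.numeric(mark_x),
    mark_times_h = as.numeric(mark_times_h),
    band_x = as.numeric(band_x),
    growth_rate_mm_per_h = growth_rate_mm_per_h,
    raw_densitometry = as.numeric(raw_densitometry)
  ), class = "tube_record")
}

#' Analyze a race-tube pack image into per-tube records
#'
#' Runs the full feature-extraction pipeline: boundary detection,
#' per-tube densitometry, the two smoothing passes, time-mark detection
#' and time assignment, mark excision, band-peak detection, and growth
#' rate. Densitometry values are stored rounded to 4 decimals, the
#' precision of the experiment-file format.
#'
#' @param img a `race_tube_image` or a path to an image file.
#' @param mark_times explicit clock times (hours) for the marks of every
#'   tube, or `NULL` to use `mark_interval`.
#' @param mark_interval fixed hours between marks (default 24, the daily
#'   marking convention) when `mark_times` is `NULL`.
#' @param measured_mm physical distance (mm) between first and last mark:
#'   a single value for all tubes or a vector per tube; `NULL` leaves the
#'   growth rate as `NA` ("N/A").
#' @param pack_name overrides the image's pack name.
#' @param boundaries a precomputed `tube_boundary_set`, or `NULL` to
#'   detect.
#' @param add_boundary,remove_boundary boundary overrides (rows), see
#'   [select_boundaries()].
#' @param add_mark,remove_mark,add_peak,remove_peak per-tube overrides:
#'   lists indexed by tube number, each a vector of x positions.
#' @return list of `tube_record`, one per tube (top-down), with the
#'   normalized image attached as attribute `"image"`.
#' @export
analyze_pack <- function(img, mark_times = NULL, mark_interval = 24,
                         measured_mm = NULL, pack_name = NULL,
                         boundaries = NULL,
                         add_boundary = NULL, remove_boundary = NULL,
                         add_mark = list(), remove_mark = list(),
                         add_peak = list(), remove_peak = list()) {
  if (is.character(img)) img <- load_race_tube(img)
  stopifnot(inherits(img, "race_tube_image"))
  if (!is.null(pack_name)) img$pack_name <- pack_name
  if (is.null(boundaries))
    boundaries <- detect_tube_boundaries(img, add = add_boundary,
                                         remove = remove_boundary)
  tubes <- boundaries$tubes
  n <- nrow(tubes)
  mm <- if (is.null(measured_mm)) rep(NA_real_, n) else rep_len(measured_mm, n)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    raw <- tube_densitometry(img, boundaries, i)
    band_sm <- smooth_for_bands(raw)
    mark_sm <- smooth_for_marks(raw)
    marks <- detect_time_marks(mark_sm,
                               add = tube_override(add_mark, i),
                               remove = tube_override(remove_mark, i))
    marks <- set_mark_times(marks, times = mark_times,
                            interval = if (is.null(mark_times)) mark_interval)
    interp <- interpolate_over_marks(band_sm, marks)
    bands <- detect_band_peaks(interp,
                               add = tube_override(add_peak, i),
                               remove = tube_override(remove_peak, i))
    gr <- if (is.na(mm[i])) NA_real_ else growth_rate(marks, mm[i])
    tb <- tubes[tubes$index == i, ]
    records[[i]] <- new_tube_record(
      pack_name = img$pack_name,
      tube_index = i,
      source_image = basename(img$source_path),
      greyscale_image_ref = "",
      tube_y_bounds = data.frame(
        which = c("top", "bottom"),
        y_left = c(tb$top_left, tb$bottom_left),
        y_right = c(tb$top_right, tb$bottom_right),
        method = c(tb$top_method, tb$bottom_method)),
      mark_x = marks$x_positions,
      mark_times_h = marks$times_h,
      band_x = bands$x_positions,
      growth_rate_mm_per_h = gr,
      raw_densitometry = round(raw$values, 4))
  }
  attr(records, "image") <- img
  records
}

# Per-tube override lookup: lists may be named by tube number or
# positional, and may be shorter than the tube count.
tube_override <- function(lst, i) {
  if (!length(lst)) return(NULL)
  nm <- names(lst)
  if (!is.null(nm) && as.character(i) %in% nm) return(lst[[as.character(i)]])
  if (is.null(nm) && length(lst) >= i) return(lst[[i]])
  NULL
}

#' Rebuild the densitometry chain of a stored record
#'
#' Recomputes the band-smoothed and interpolated profiles from the
#' record's raw densitometry and stored mark positions.
#'
#' @param record a `tube_record`.
#' @return list with profiles `raw`, `band_smoothed`, `interpolated`.
#' @export
record_profiles <- function(record) {
  stopifnot(inherits(record, "tube_record"))
  raw <- new_profile(record$raw_densitometry, "raw", record$tube_index)
  band_sm <- smooth_for_bands(raw)
  interp <- interpolate_over_marks(band_sm, record_marks(record))
  list(raw = raw, band_smoothed = band_sm, interpolated = interp)
}

#' Time marks of a stored record
#' @param record a `tube_record`.
#' @return a `time_mark_set`.
#' @export
record_marks <- function(record) {
  new_time_marks(record$mark_x, record$mark_times_h)
}

#' @export
print.tube_record <- function(x, ...) {
  cat(sprintf("tube_record: pack '%s' tube %d, %d marks, %d band peaks, growth %s\n",
              x$pack_name, x$tube_index, length(x$mark_x), length(x$band_x),
              if (is.na(x$growth_rate_mm_per_h)) "N/A"
              else sprintf("%.3f mm/h", x$growth_rate_mm_per_h)))
  invisible(x)
}
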