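# Synthetic race-tube pack generator.
#
# Emulates the anatomy of a scanned six-pack: parallel horizontal tubes
# separated by thin dark margins, a slight bright-to-dark brightness ramp
# along the growth axis, raised-cosine conidial bands of known spatial
# period, thin dark vertical pen marks at known positions, and additive
# Gaussian pixel noise. Ground truth (boundary rows, per-tube mark
# positions/times, analytic band-peak positions) is returned alongside so
# every detector and estimator can be validated without real scans.
#
# Bands are raised cosines rather than square pulses: conidial density in
# real scans grades smoothly, and smooth peaks exercise the width and
# prominence criteria of the peak detectors. Banding starts at the first
# time mark (cultures are synchronized at the transfer to darkness) and
# the band field ends on a trough so no half-formed peak sits at the end
# of the growth region.

#' Specification for a synthetic race-tube pack
#'
#' Defaults describe a realistic wild-type-like pack: six tubes, a
#' 22.5 h free-running period, growth of 4.1667 px/h (so a 24 h mark
#' interval spans 100 px and the image holds ~11 days), band contrast 60
#' brightness units, pen marks jittered by about a pixel, and mild
#' scanner noise (sd 8).
#'
#' @param n_tubes number of tubes (>= 1).
#' @param true_period_h free-running period in hours.
#' @param growth_px_per_h growth rate in px/h.
#' @param mark_interval_h hours between pen marks.
#' @param first_mark_x column of the first mark (time 0).
#' @param mark_jitter_px sd of mark placement noise, px.
#' @param band_contrast peak-to-trough band amplitude, brightness units.
#' @param background base brightness.
#' @param ramp half-amplitude of the linear bright-to-dark gradient along
#'   the tube (brightness declines by `2 * ramp` across the width).
#' @param noise_sd additive Gaussian pixel noise sd.
#' @param boundary_darkness brightness of the inter-tube margin lines.
#' @param boundary_thickness margin line thickness, px.
#' @param mark_darkness brightness of the pen strokes.
#' @param mark_width_px pen stroke width, px.
#' @param tilt_px vertical drift of the boundary lines across the image.
#' @param band_phase_frac offset of the first band peak after the first
#'   mark, as a fraction of the band spatial period.
#' @param taper_px length of the raised-cosine onset taper of the band
#'   field.
#' @param seed RNG seed; fixed seed gives a bit-identical pack.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_tubes = 6, true_period_h = 22.5,
                           growth_px_per_h = 4.1667, mark_interval_h = 24,
                           first_mark_x = 40, mark_jitter_px = 1,
                           band_contrast = 60, background = 120, ramp = 15,
                           noise_sd = 8, boundary_darkness = 30,
                           boundary_thickness = 2, mark_darkness = 20,
                           mark_width_px = 3, tilt_px = 0,
                           band_phase_frac = 0.35, taper_px = 20,
                           seed = NULL) {
  spec <- list(n_tubes = n_tubes, true_period_h = true_period_h,
               growth_px_per_h = growth_px_per_h,
               mark_interval_h = mark_interval_h,
               first_mark_x = first_mark_x, mark_jitter_px = mark_jitter_px,
               band_contrast = band_contrast, background = background,
               ramp = ramp, noise_sd = noise_sd,
               boundary_darkness = boundary_darkness,
               boundary_thickness = boundary_thickness,
               mark_darkness = mark_darkness, mark_width_px = mark_width_px,
               tilt_px = tilt_px, band_phase_frac = band_phase_frac,
               taper_px = taper_px, seed = seed)
  if (spec$n_tubes < 1) rt_error("need at least 1 tube", "rt_input_error")
  lambda <- spec$true_period_h * spec$growth_px_per_h
  if (lambda < 20)
    rt_error(sprintf("band spatial period %.1f px is below the 20 px resolution floor",
                     lambda), "rt_resolution_error")
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic race-tube pack with ground truth
#'
#' @param spec a `synthetic_spec` (or arguments for one via `...`).
#' @param ... used to build a spec when `spec` is missing.
#' @return list with `image` (a `race_tube_image`) and `truth`: boundary
#'   line rows, per-tube mark positions/times and analytic band-peak
#'   positions, the band spatial period (`lambda_px`) and the generating
#'   spec.
#' @export
generate_pack <- function(spec = NULL, ...) {
  if (is.null(spec)) spec <- synthetic_spec(...)
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  W <- RT_WIDTH; H <- RT_HEIGHT
  n <- spec$n_tubes
  th <- spec$boundary_thickness
  v <- spec$growth_px_per_h
  lambda <- spec$true_period_h * v

  xs <- seq_len(W)
  base_col <- spec$background + spec$ramp - 2 * spec$ramp * (xs - 1) / (W - 1)
  canvas <- matrix(rep(base_col, each = H), H, W)

  # boundary lines (n + 1, including outer top and bottom)
  y_lines <- round(seq(1, H - th + 1, length.out = n + 1))
  tilt_off <- as.integer(round(spec$tilt_px * (xs - 1) / (W - 1)))
  for (k in seq_along(y_lines)) {
    for (o in unique(tilt_off)) {
      cols <- xs[tilt_off == o]
      rows <- pmin(pmax(y_lines[k] + o + seq_len(th) - 1L, 1L), H)
      canvas[rows, cols] <- spec$boundary_darkness
    }
  }

  # mark schedule shared across tubes (times), positions jittered per tube
  n_marks <- floor((W - 10 - spec$first_mark_x) / (v * spec$mark_interval_h)) + 1
  if (n_marks < 2)
    rt_error("fewer than 2 marks fit in the image; lower the growth rate",
             "rt_input_error")
  times_h <- spec$mark_interval_h * (seq_len(n_marks) - 1)
  nominal_x <- spec$first_mark_x + v * times_h

  tubes <- vector("list", n)
  for (i in seq_len(n)) {
    mx <- round(nominal_x + rnorm(n_marks, 0, spec$mark_jitter_px))
    mx <- pmin(pmax(mx, 2L), W - spec$mark_width_px)
    for (k in seq_len(n_marks)[-1])            # keep strictly increasing
      if (mx[k] <= mx[k - 1]) mx[k] <- mx[k - 1] + 1L
    x_first <- mx[1]; x_last <- mx[n_marks]

    # band field: peaks at p_k = x_first + (phase + k) * lambda while the
    # trailing trough still fits before the last mark
    p0 <- x_first + spec$band_phase_frac * lambda
    peaks <- p0 + lambda * (0:floor((x_last - lambda / 2 - p0) / lambda))
    peaks <- peaks[peaks + lambda / 2 <= x_last]
    field_end <- if (length(peaks)) max(peaks) + lambda / 2 else x_first
    band <- numeric(W)
    if (spec$band_contrast > 0 && length(peaks)) {
      reg <- xs >= x_first & xs <= field_end
      band[reg] <- spec$band_contrast / 2 *
        (1 + cos(2 * pi * (xs[reg] - p0) / lambda))
      tap <- xs >= x_first & xs < x_first + spec$taper_px
      band[tap] <- band[tap] *
        0.5 * (1 - cos(pi * (xs[tap] - x_first) / spec$taper_px))
    }

    # tube interior rows between line k = i and k = i + 1 (tilt handled
    # column-block-wise below)
    r_top0 <- y_lines[i] + th           # first interior row at tilt 0
    r_bot0 <- y_lines[i + 1] - 1L
    for (o in unique(tilt_off)) {
      cols <- xs[tilt_off == o]
      rows <- pmin(pmax((r_top0:r_bot0) + o, 1L), H)
      canvas[rows, cols] <- rep(base_col[cols] + band[cols],
                                each = length(rows))
      # pen strokes overwrite the tube content
      for (m in mx) {
        mc <- intersect(cols, m:(m + spec$mark_width_px - 1L))
        if (length(mc)) canvas[rows, mc] <- spec$mark_darkness
      }
    }

    tubes[[i]] <- list(mark_x = mx + (spec$mark_width_px - 1) / 2,
                       times_h = times_h, band_peaks_x = peaks)
  }

  if (spec$noise_sd > 0)
    canvas <- canvas + matrix(rnorm(H * W, 0, spec$noise_sd), H, W)
  canvas <- round(pmin(pmax(canvas, 0), 255))
  storage.mode(canvas) <- "integer"

  img <- new_race_tube_image(canvas, source_path = "",
                             pack_name = "synthetic", orientation_applied = "none")
  truth <- list(
    boundary_y = data.frame(
      y_left = y_lines + (th - 1) / 2,
      y_right = y_lines + (th - 1) / 2 + spec$tilt_px),
    tubes = tubes,
    lambda_px = lambda,
    hours_per_px = 1 / v,
    spec = spec)
  structure(list(image = img, truth = truth), class = "synthetic_pack")
}

#' Write a synthetic pack to disk
#'
#' Saves the normalized greyscale image as a PNG and the ground-truth
#' bundle as JSON next to it.
#'
#' @param pack a `synthetic_pack` from [generate_pack()].
#' @param png_path output image path; the truth JSON gets the same stem
#'   with extension `.truth.json`.
#' @return invisibly, the two paths written.
#' @export
write_pack <- function(pack, png_path) {
  stopifnot(inherits(pack, "synthetic_pack"))
  write_greyscale_png(pack$image, png_path)
  truth_path <- paste0(sub("\\.png$", "", png_path), ".truth.json")
  truth <- pack$truth
  truth$spec <- unclass(truth$spec)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(image = png_path, truth = truth_path))
}
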