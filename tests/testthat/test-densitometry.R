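make_two_tube_set <- function() {
  mk <- function(ys) data.frame(y_left = ys, y_right = ys,
                                method = rep("canny_hough", length(ys)),
                                stringsAsFactors = FALSE)
  select_boundaries(mk(c(100, 200)), mk(numeric(0)))
}

test_that("tube densitometry averages the correct rows", {
  m <- matrix(0, 400, 1160)
  m[101:199, ] <- 100                       # tube between lines 100 and 200
  img <- as_race_tube(m)
  bs <- make_two_tube_set()
  p <- tube_densitometry(img, bs, 2)        # middle region
  expect_s3_class(p, "densitometry_profile")
  expect_length(p$values, 1160)
  expect_true(all(p$values == 100))

  # step: left half dark, right half bright inside the tube
  m2 <- matrix(0, 400, 1160)
  m2[101:199, 581:1160] <- 200
  p2 <- tube_densitometry(as_race_tube(m2), bs, 2)
  expect_true(all(p2$values[1:580] == 0))
  expect_true(all(p2$values[581:1160] == 200))
})

test_that("the profile of a synthetic tube tracks the generated band signal", {
  pk <- fx_pack(seed = 21, noise_sd = 0)
  bs <- detect_tube_boundaries(pk$image)
  p <- tube_densitometry(pk$image, bs, 1)
  tt <- pk$truth$tubes[[1]]
  sp <- pk$truth$spec
  lam <- pk$truth$lambda_px
  xs <- seq(ceiling(min(tt$band_peaks_x)), floor(max(tt$band_peaks_x)))
  # mark strokes overwrite the band signal; exclude their columns
  near_mark <- vapply(xs, function(x) any(abs(x - tt$mark_x) <= 4),
                      logical(1))
  xs <- xs[!near_mark]
  base <- sp$background + sp$ramp - 2 * sp$ramp * (xs - 1) / (1160 - 1)
  band <- sp$band_contrast / 2 *
    (1 + cos(2 * pi * (xs - tt$band_peaks_x[1]) / lam))
  expect_gt(cor(p$values[xs] - base, band), 0.9)
})

test_that("Savitzky-Golay filters are exact for low-order polynomials", {
  const <- fx_profile(rep(150, 300))
  expect_equal(smooth_for_bands(const)$values, rep(150, 300))
  expect_equal(smooth_for_marks(const)$values, rep(150, 300))

  x <- seq_len(300)
  quartic <- 100 + 0.5 * x - 3e-3 * x^2 + 1e-5 * x^3 - 1.5e-8 * x^4
  expect_equal(smooth_for_bands(fx_profile(quartic))$values, quartic,
               tolerance = 1e-8)
  cubic <- 60 + 0.3 * x - 1e-3 * x^2 + 1e-6 * x^3
  expect_equal(smooth_for_marks(fx_profile(cubic))$values, cubic,
               tolerance = 1e-4)
  expect_error(smooth_for_bands(const, window = 3, order = 4),
               class = "rt_config_error")
})

test_that("band smoothing reduces noise around a sinusoid", {
  set.seed(8)
  x <- seq_len(1160)
  clean <- 150 + 30 * sin(2 * pi * x / 94)
  noisy <- clean + rnorm(1160, 0, 10)
  sm <- smooth_for_bands(fx_profile(noisy))$values
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(rms(sm - clean), rms(noisy - clean))
})

test_that("the mark filter preserves a narrow notch far better than the band filter", {
  v <- rep(150, 1160); v[499:501] <- 50
  d_mark <- 150 - min(smooth_for_marks(fx_profile(v))$values)
  d_band <- 150 - min(smooth_for_bands(fx_profile(v))$values)
  expect_gt(d_mark, 50)          # keeps over half the 100-unit depth
  expect_gt(d_mark, 1.5 * d_band)
})

test_that("time marks are found at notches and not on flat or band-like profiles", {
  expect_length(detect_time_marks(fx_profile(rep(120, 1160)))$x_positions, 0)

  v <- rep(150, 1160); v[498:502] <- 40
  mk <- detect_time_marks(smooth_for_marks(fx_profile(v)))
  expect_equal(mk$x_positions, 500)

  # broad gentle band troughs must not register as marks
  x <- seq_len(1160)
  band <- 150 + 25 * cos(2 * pi * x / 94)
  mk2 <- detect_time_marks(smooth_for_marks(fx_profile(band)))
  expect_length(mk2$x_positions, 0)
})

test_that("synthetic marks are recovered within 2 px with none at band troughs", {
  pk <- fx_pack(seed = 42)
  recs <- fx_records(seed = 42)
  for (i in seq_along(recs)) {
    tt <- pk$truth$tubes[[i]]
    expect_length(recs[[i]]$mark_x, length(tt$mark_x))
    expect_true(all(abs(recs[[i]]$mark_x - tt$mark_x) <= 2))
  }
})

test_that("mark interpolation is the identity off-window and on degenerate bridges", {
  # no marks -> identity
  set.seed(3)
  v <- runif(1160, 50, 200)
  p <- fx_profile(v, "band_smoothed")
  expect_equal(interpolate_over_marks(p, fx_marks(numeric(0)))$values, v)

  # flat profile with a notch -> exactly flat
  f <- rep(150, 1160); f[500] <- 20
  out <- interpolate_over_marks(fx_profile(f, "band_smoothed"), fx_marks(500))
  expect_equal(out$values, rep(150, 1160))

  # ramp with notch -> ramp (bridge endpoints are collinear)
  r <- seq_len(1160) / 10; rn <- r; rn[500] <- 0
  out2 <- interpolate_over_marks(fx_profile(rn, "band_smoothed"), fx_marks(500))
  expect_equal(out2$values, r)

  # pointwise identity outside the union of exclusion windows
  for (k in 1:10) {
    v <- runif(1160, 0, 255)
    marks <- sort(sample(20:1140, sample(2:12, 1)))
    w <- 12
    out <- interpolate_over_marks(fx_profile(v, "band_smoothed"),
                                  fx_marks(marks), half_width = w)
    inside <- rep(FALSE, 1160)
    for (m in marks) inside[max(1, m - w):min(1160, m + w)] <- TRUE
    expect_identical(out$values[!inside], v[!inside])
  }
})

test_that("band peaks land on analytic sinusoid maxima and reject narrow spikes", {
  expect_length(detect_band_peaks(fx_profile(rep(90, 1160)))$x_positions, 0)

  # 10 full cycles, peaks at 47 + k * 94  (maxima of cos(2 pi (x-47)/94))
  x <- seq_len(940 + 94)
  v <- 150 + 30 * cos(2 * pi * (x - 47) / 94)
  pk <- detect_band_peaks(fx_profile(v, "interpolated"))
  truth <- 47 + 94 * (0:10)
  expect_length(pk$x_positions, length(truth))
  expect_true(all(abs(pk$x_positions - truth) <= 1))

  # a 2-px-wide spike (placed on a trough so it masks no real peak's
  # prominence) is rejected by the width criterion
  v2 <- v; v2[470:471] <- v2[470:471] + 80
  pk2 <- detect_band_peaks(fx_profile(v2, "interpolated"))
  expect_length(pk2$x_positions, length(truth))
  expect_true(all(abs(pk2$x_positions - truth) <= 1))
})

test_that("band count matches ground truth on synthetic tubes and detection is deterministic", {
  pk <- fx_pack(seed = 42)
  recs <- fx_records(seed = 42)
  for (i in seq_along(recs))
    expect_length(recs[[i]]$band_x, length(pk$truth$tubes[[i]]$band_peaks_x))
  r2 <- analyze_pack(pk$image)
  expect_identical(lapply(recs, `[[`, "band_x"), lapply(r2, `[[`, "band_x"))
})
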