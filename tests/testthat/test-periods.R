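test_that("slice_window restricts profile and marks consistently", {
  v <- seq_len(1160)
  p <- fx_profile(v, "interpolated")
  marks <- fx_marks(c(100, 200, 300), c(0, 24, 48))

  full <- slice_window(p, marks, 1, 3)
  expect_equal(full$profile$values, v[100:300])
  expect_equal(full$profile$x_offset, 99)
  expect_equal(full$marks$x_positions, c(100, 200, 300))

  sub <- slice_window(p, marks, 1, 2)
  expect_equal(sub$profile$values, v[100:200])
  expect_equal(sub$marks$times_h, c(0, 24))

  expect_error(slice_window(p, marks, 2, 2), class = "rt_window_error")
  expect_error(slice_window(p, marks, 3, 1), class = "rt_window_error")
})

test_that("linear-regression period is mean band spacing times hours-per-px", {
  cal <- fx_cal(0.24)
  est <- period_linear_regression(
    structure(list(x_positions = c(150, 243.75)), class = "band_peak_set"),
    cal)
  expect_equal(est$period_h, 22.5)

  cal2 <- fx_cal(0.225)
  est2 <- period_linear_regression(
    structure(list(x_positions = c(100, 200, 300)), class = "band_peak_set"),
    cal2)
  expect_equal(est2$period_h, 22.5)

  expect_error(period_linear_regression(
    structure(list(x_positions = 150), class = "band_peak_set"), cal),
    class = "rt_insufficient_peaks")
})

test_that("the Sokolove-Bushell implementation matches its literal loop transcription", {
  cal <- fx_cal(0.24)
  set.seed(17)
  for (k in 1:6) {
    n <- sample(300:1200, 1)
    v <- runif(n, 0, 255)
    pg <- periodogram_sokolove_bushell(v, cal)
    periods_px <- round(pg$periods_h / cal$hours_per_px)
    expect_lt(max(abs(pg$power - oracle_sb(v, periods_px)) /
                    pmax(abs(pg$power), 1e-12)), 1e-9)
  }
})

test_that("Sokolove-Bushell peaks at the true period of a square wave", {
  cal <- fx_cal(0.24)
  v <- rep(c(rep(1, 47), rep(0, 47)), length.out = 1128)
  pg <- periodogram_sokolove_bushell(v, cal)
  expect_equal(pg$peak_period_h, 94 * 0.24)
  expect_error(periodogram_sokolove_bushell(rep(5, 1000), cal),
               class = "rt_degenerate_series")
})

test_that("the Lomb-Scargle implementation matches its literal loop transcription", {
  cal <- fx_cal(0.24)
  set.seed(23)
  for (k in 1:4) {
    n <- sample(200:800, 1)
    v <- runif(n, 0, 255)
    pg <- periodogram_lomb_scargle(v, cal, oversample = 4)
    freqs <- 1 / (pg$periods_h / cal$hours_per_px)
    expect_lt(max(abs(pg$power - oracle_ls(v, freqs)) /
                    pmax(abs(pg$power), 1e-12)), 1e-9)
  }
})

test_that("Lomb-Scargle finds a sinusoid's period with power about N/4", {
  cal <- fx_cal(0.24)
  n <- 1128
  v <- sin(2 * pi * (0:(n - 1)) / 94)
  pg <- periodogram_lomb_scargle(v, cal)
  expect_equal(pg$peak_period_h / cal$hours_per_px, 94, tolerance = 0.01)
  expect_equal(max(pg$power), n / 4, tolerance = 0.05)
  expect_error(periodogram_lomb_scargle(rep(3, 1000), cal),
               class = "rt_degenerate_series")
})

test_that("CWT recovers a stationary period with near-zero slope and signs a chirp", {
  cal <- fx_cal(0.24)
  n <- 1128
  v <- sin(2 * pi * (0:(n - 1)) / 94)
  cw <- cwt_analysis(v, cal)
  expect_equal(cw$period_h, 94 * 0.24, tolerance = 0.05)
  expect_lt(abs(cw$slope), 0.02)
  expect_true(all(cw$ridge$amplitude[cw$ridge$accepted] >
                    0.75 * max(cw$amplitude)))
  expect_equal(cw$period_h, mean(cw$ridge$period_h[cw$ridge$accepted]))

  inst_p <- 80 + 30 * (0:(n - 1)) / (n - 1)
  chirp <- sin(cumsum(2 * pi / inst_p))
  expect_gt(cwt_analysis(chirp, cal)$slope, 0)

  expect_error(cwt_analysis(rep(1, 1000), cal),
               class = "rt_degenerate_series")
})

test_that("periodogram peak location commutes with the px-to-hour conversion", {
  cal <- fx_cal(0.21)
  set.seed(4)
  v <- 150 + 30 * sin(2 * pi * (0:999) / 100) + rnorm(1000, 0, 5)
  pg <- periodogram_sokolove_bushell(v, cal)
  px_grid <- pg$periods_h / cal$hours_per_px
  expect_equal(pg$peak_period_h,
               px_grid[which.max(pg$power)] * cal$hours_per_px)
  pl <- periodogram_lomb_scargle(v, cal)
  expect_equal(pl$peak_period_h,
               (pl$periods_h / cal$hours_per_px)[which.max(pl$power)] *
                 cal$hours_per_px)
})

test_that("all four estimators agree on a synthetic 22.5 h tube", {
  recs <- fx_records(seed = 42)
  per <- all_periods(recs[[1]])
  expect_equal(per$method, c("linear_regression", "sokolove_bushell",
                             "lomb_scargle", "cwt"))
  expect_true(all(is.na(per$error)))
  expect_true(all(per$period_h > 22 & per$period_h < 23))
  # determinism
  expect_identical(per, all_periods(recs[[1]]))
})

test_that("estimators fail independently inside a too-narrow window", {
  recs <- fx_records(seed = 42)
  # a one-interval window holds at most one band peak
  per <- all_periods(recs[[1]], window = c(1, 2))
  lr <- per[per$method == "linear_regression", ]
  expect_true(is.na(lr$period_h))
  expect_match(lr$error, "peak|band")
  # the spectral methods error too (window shorter than 2x max period) or
  # return a value; either way they must not abort the whole call
  expect_equal(nrow(per), 4)
})

test_that("noiseless estimates are mutually consistent within 0.5 h", {
  recs <- analyze_pack(fx_pack(seed = 7, noise_sd = 0,
                               mark_jitter_px = 0)$image)
  for (r in recs) {
    per <- all_periods(r)
    expect_lt(max(per$period_h) - min(per$period_h), 0.5)
  }
})
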