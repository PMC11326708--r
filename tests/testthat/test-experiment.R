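test_that("experiment files round-trip losslessly and byte-identically", {
  recs <- fx_records(seed = 42)
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "exp.json")
  save_experiment(recs, f1)
  loaded <- load_experiment(f1)
  expect_length(loaded, length(recs))
  for (i in seq_along(recs)) {
    for (fld in c("pack_name", "tube_index", "mark_x", "mark_times_h",
                  "band_x", "raw_densitometry"))
      expect_equal(loaded[[i]][[fld]], recs[[i]][[fld]])
    expect_equal(loaded[[i]]$growth_rate_mm_per_h,
                 recs[[i]]$growth_rate_mm_per_h)
  }
  # write -> read -> write is byte-identical
  f2 <- file.path(dir, "exp2.json")
  save_experiment(loaded, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("an empty record list produces a valid zero-tube file", {
  f <- withr::local_tempfile(fileext = ".json")
  save_experiment(list(), f)
  expect_length(load_experiment(f), 0)
})

test_that("records from two packs append with pack names preserved", {
  a <- fx_records(seed = 42)
  b <- analyze_pack(fx_pack(seed = 43)$image, pack_name = "packB")
  f <- withr::local_tempfile(fileext = ".json")
  save_experiment(c(a, b), f)
  loaded <- load_experiment(f)
  expect_length(loaded, 12)
  expect_equal(unique(vapply(loaded, `[[`, "", "pack_name")),
               c("synthetic", "packB"))
})

test_that("unknown schema versions are rejected", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(schema_version = "99.0", tubes = list()), f,
                       auto_unbox = TRUE)
  expect_error(load_experiment(f), class = "rt_schema_error")
  expect_error(load_experiment("no/such/exp.json"), class = "rt_io_error")
})

test_that("periods are derived, so editing a stored mark shifts the LR period", {
  recs <- fx_records(seed = 42)
  f <- withr::local_tempfile(fileext = ".json")
  save_experiment(recs[1], f)
  loaded <- load_experiment(f)
  before <- all_periods(loaded[[1]])
  lr0 <- before$period_h[before$method == "linear_regression"]
  # squeeze the last mark inward: px/h drops, hours/px grows, LR period grows
  r <- loaded[[1]]
  r$mark_x[length(r$mark_x)] <- r$mark_x[length(r$mark_x)] - 20
  after <- all_periods(r)
  lr1 <- after$period_h[after$method == "linear_regression"]
  expect_gt(lr1, lr0)
})

test_that("export writes the full file inventory and CSVs reload exactly", {
  recs <- fx_records(seed = 42)[1]
  dir <- withr::local_tempdir()
  inv <- export_all(recs, dir)
  expect_equal(sum(inv$type == "csv"), 5)     # dens, sb, ls, cwt, periods
  expect_equal(sum(inv$type == "plot"), 4)
  expect_true(all(file.exists(inv$file)))

  dens <- read.csv(grep("densitometry.csv", inv$file, value = TRUE))
  pr <- record_profiles(recs[[1]])
  expect_equal(dens$raw, pr$raw$values)
  expect_equal(dens$interpolated, pr$interpolated$values)

  per <- read.csv(file.path(dir, "periods.csv"))
  expect_equal(nrow(per), 4)
  expect_true(all(is.na(per$growth_rate_mm_per_h)))
})

test_that("export survives a degenerate flat tube", {
  flat <- structure(list(
    pack_name = "flat", tube_index = 1L, source_image = "",
    greyscale_image_ref = "",
    tube_y_bounds = data.frame(which = c("top", "bottom"),
                               y_left = c(100, 200), y_right = c(100, 200),
                               method = "canny_hough"),
    mark_x = c(100, 340, 580, 820), mark_times_h = c(0, 24, 48, 72),
    band_x = numeric(0), growth_rate_mm_per_h = NA_real_,
    raw_densitometry = rep(150, 1160)), class = "tube_record")
  dir <- withr::local_tempdir()
  expect_no_error(inv <- export_all(list(flat), dir))
  per <- read.csv(file.path(dir, "periods.csv"))
  expect_true(all(is.na(per$period_h)))       # every estimator errors
})
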