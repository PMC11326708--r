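test_that("constant images give no edges, no lines, and a no-tubes error", {
  img <- as_race_tube(matrix(128, 400, 1160))
  edges <- detect_canny_edges(img)
  expect_false(any(edges))
  a <- boundaries_from_hough(edges)
  expect_equal(nrow(a), 0)
  b <- boundaries_from_vertical_density(img)
  expect_equal(nrow(b), 0)
  expect_error(select_boundaries(a, b), class = "rt_no_tubes_error")
})

test_that("a hard horizontal step produces a contiguous horizontal edge", {
  m <- matrix(255, 400, 1160)
  m[200:400, ] <- 0
  edges <- detect_canny_edges(as_race_tube(m))
  rows <- rowSums(edges)
  expect_gt(max(rows[195:205]), 1000)   # near-full-width edge at the step
  expect_true(all(rows[-(190:210)] < 50))
})

test_that("a single full-width edge row yields one full-width boundary line", {
  edges <- matrix(FALSE, 400, 1160)
  edges[200, ] <- TRUE
  lines <- boundaries_from_hough(edges)
  expect_equal(nrow(lines), 1)
  expect_equal(lines$y_left, 200)
  expect_equal(lines$y_right, 200)
})

test_that("seven dark full-width rows yield seven vertical-density lines", {
  m <- matrix(200, 400, 1160)
  rows <- c(20, 80, 140, 200, 260, 320, 380)
  m[rows, ] <- 30
  b <- boundaries_from_vertical_density(as_race_tube(m))
  expect_equal(nrow(b), 7)
  expect_equal(sort(b$y_left), rows, tolerance = 1e-8)
})

test_that("tilted boundaries are recovered with their tilt", {
  pk <- fx_pack(seed = 3, tilt_px = 2, noise_sd = 0)
  b <- boundaries_from_vertical_density(pk$image)
  expect_gte(nrow(b), 4)
  slopes <- b$y_right - b$y_left
  expect_true(all(abs(slopes - 2) < 1.5))
})

test_that("both detectors find synthetic boundaries within 3 px", {
  pk <- fx_pack(seed = 42)
  truth_y <- (pk$truth$boundary_y$y_left + pk$truth$boundary_y$y_right) / 2
  interior <- truth_y[2:(length(truth_y) - 1)]

  a <- boundaries_from_hough(detect_canny_edges(pk$image))
  expect_gte(nrow(a), 5); expect_lte(nrow(a), 7)
  for (y in interior)
    expect_lt(min(abs((a$y_left + a$y_right) / 2 - y)), 3)

  b <- boundaries_from_vertical_density(pk$image)
  for (y in interior)
    expect_lt(min(abs((b$y_left + b$y_right) / 2 - y)), 3)
})

test_that("select_boundaries keeps the larger set, prefers Canny on ties, dedups", {
  mk <- function(ys, method) data.frame(y_left = ys, y_right = ys,
                                        method = method,
                                        stringsAsFactors = FALSE)
  a7 <- mk(c(1, 67, 134, 200, 266, 333, 399), "canny_hough")
  b4 <- mk(c(67, 200, 266, 333), "vertical_density")
  s <- select_boundaries(a7, b4)
  expect_equal(nrow(s$lines), 7)
  expect_true(all(s$lines$method == "canny_hough"))
  expect_equal(nrow(s$tubes), 6)

  # tie -> canny list
  b7 <- mk(c(1, 67, 134, 200, 266, 333, 399), "vertical_density")
  s2 <- select_boundaries(a7, b7)
  expect_true(all(s2$lines$method == "canny_hough"))

  # near-duplicates collapse to one copy each
  a_dup <- mk(c(1, 2, 67, 68, 134, 200, 266, 333, 399), "canny_hough")
  s3 <- select_boundaries(a_dup, b4)
  expect_equal(nrow(s3$lines), 7)

  # overrides are applied after selection
  s4 <- select_boundaries(a7, b4, remove = 134, add = 100)
  expect_true(100 %in% s4$lines$y_left)
  expect_false(134 %in% s4$lines$y_left)
})

test_that("selection is deterministic and boundary recovery is accurate across random packs", {
  set.seed(31)
  n_checked <- 0; n_ok <- 0
  for (k in 1:8) {
    nt <- sample(3:8, 1)
    pk <- generate_pack(synthetic_spec(seed = 300 + k, n_tubes = nt,
                                       noise_sd = runif(1, 0, 10)))
    s1 <- detect_tube_boundaries(pk$image)
    s2 <- detect_tube_boundaries(pk$image)
    expect_identical(s1, s2)
    expect_equal(nrow(s1$tubes), nt)
    ty <- (pk$truth$boundary_y$y_left + pk$truth$boundary_y$y_right) / 2
    for (y in ty[2:(length(ty) - 1)]) {
      d <- min(abs((s1$lines$y_left + s1$lines$y_right) / 2 - y))
      n_checked <- n_checked + 1
      if (d <= 3) n_ok <- n_ok + 1
    }
  }
  expect_gte(n_ok / n_checked, 0.95)
})
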