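# Shared fixtures. Packs are generated once per test run and cached by
# argument signature; all randomness is seeded through synthetic_spec.

.fixture_cache <- new.env(parent = emptyenv())

fx_pack <- function(seed = 42, ...) {
  key <- paste(seed, paste(deparse(list(...)), collapse = ""), sep = "|")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_pack(synthetic_spec(seed = seed, ...))
  .fixture_cache[[key]]
}

fx_records <- function(seed = 42, ...) {
  key <- paste("rec", seed, paste(deparse(list(...)), collapse = ""), sep = "|")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- analyze_pack(fx_pack(seed, ...)$image)
  .fixture_cache[[key]]
}

# calibration with a given hours-per-px from two synthetic marks
fx_cal <- function(hours_per_px = 0.24) {
  marks <- structure(list(x_positions = c(100, 100 + 24 / hours_per_px),
                          times_h = c(0, 24)),
                     class = "time_mark_set")
  fit_time_calibration(marks)
}

# profile object from a bare numeric vector
fx_profile <- function(values, variant = "raw", tube_index = 1L) {
  structure(list(values = as.numeric(values), variant = variant,
                 tube_index = as.integer(tube_index), x_offset = 0L),
            class = "densitometry_profile")
}

fx_marks <- function(x, times = NULL) {
  structure(list(x_positions = as.numeric(x), times_h = times),
            class = "time_mark_set")
}

# Literal loop-based transcription of the Sokolove-Bushell statistic:
# independent oracle for the vectorized implementation.
oracle_sb <- function(v, periods_px) {
  vapply(periods_px, function(P) {
    K <- floor(length(v) / P)
    X <- v[1:(K * P)]
    N <- K * P
    Xbar <- mean(X)
    ss_h <- 0
    for (h in 1:P) {
      vals_h <- numeric(K)
      for (k in 1:K) vals_h[k] <- X[(k - 1) * P + h]
      ss_h <- ss_h + (mean(vals_h) - Xbar)^2
    }
    ss <- 0
    for (i in 1:N) ss <- ss + (X[i] - Xbar)^2
    K * ss_h / (ss / (N - 1))
  }, numeric(1))
}

# Literal transcription of the Lomb-Scargle power at given frequencies
# (per-sample units), mean-centred internally.
oracle_ls <- function(v, freqs) {
  x <- v - mean(v)
  tt <- seq_along(v) - 1
  vapply(freqs, function(f) {
    w <- 2 * pi * f
    s2 <- 0; c2 <- 0
    for (t in tt) { s2 <- s2 + sin(2 * w * t); c2 <- c2 + cos(2 * w * t) }
    tau <- atan2(s2, c2) / (2 * w)
    a1 <- 0; a2 <- 0; b1 <- 0; b2 <- 0
    for (j in seq_along(tt)) {
      ct <- cos(w * (tt[j] - tau)); st <- sin(w * (tt[j] - tau))
      a1 <- a1 + x[j] * ct; a2 <- a2 + ct^2
      b1 <- b1 + x[j] * st; b2 <- b2 + st^2
    }
    0.5 * (a1^2 / a2 + b1^2 / b2)
  }, numeric(1))
}
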