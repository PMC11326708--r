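# Local-extremum detection with prominence and width criteria.
#
# Peak prominence: height of a peak above the higher of the two minima
# separating it from taller terrain (or the signal edge). Peak width:
# measured at half prominence by linear interpolation. These are the
# standard definitions used by signal-processing peak finders; no
# installed R package offers both, so they are implemented here.

# Indices of strict local maxima; flat-topped plateaus yield their
# (rounded-down) midpoint, so an interpolated bridge over a clipped peak
# still counts as exactly one peak.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i < n) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) {
        out <- c(out, (i + j) %/% 2L)
        i <- j
      }
    }
    i <- i + 1L
  }
  out
}

peak_prominence <- function(x, idx) {
  n <- length(x)
  vapply(idx, function(i) {
    h <- x[i]
    # walk left to the previous point higher than the peak (or edge)
    lb <- 1L
    for (j in seq(i - 1L, 1L)) {
      if (x[j] > h) { lb <- j; break }
      if (j == 1L) lb <- 1L
    }
    left_min <- min(x[lb:i])
    rb <- n
    if (i < n) for (j in seq(i + 1L, n)) {
      if (x[j] > h) { rb <- j; break }
      if (j == n) rb <- n
    }
    right_min <- min(x[i:rb])
    h - max(left_min, right_min)
  }, numeric(1))
}

# Width at (peak height - rel_height * prominence), interpolated.
peak_width <- function(x, idx, prominence, rel_height = 0.5) {
  n <- length(x)
  mapply(function(i, p) {
    href <- x[i] - rel_height * p
    # left crossing
    jl <- i
    while (jl > 1L && x[jl - 1L] >= href && x[jl - 1L] <= x[i]) jl <- jl - 1L
    left <- if (jl > 1L && x[jl - 1L] < href) {
      (jl - 1L) + (href - x[jl - 1L]) / (x[jl] - x[jl - 1L])
    } else jl
    jr <- i
    while (jr < n && x[jr + 1L] >= href && x[jr + 1L] <= x[i]) jr <- jr + 1L
    right <- if (jr < n && x[jr + 1L] < href) {
      jr + (x[jr] - href) / (x[jr] - x[jr + 1L])
    } else jr
    right - left
  }, idx, prominence)
}

#' Find peaks by prominence and width
#'
#' Locates local maxima of a 1-d signal and filters them by topographic
#' prominence and by width at half prominence.
#'
#' @param x numeric vector.
#' @param min_prominence minimum prominence (same units as `x`).
#' @param min_width minimum width at half prominence, in samples.
#' @return data.frame with columns `index`, `height`, `prominence`,
#'   `width`, one row per accepted peak, ordered by index.
#' @export
find_peaks <- function(x, min_prominence = 0, min_width = 0) {
  idx <- local_maxima(x)
  if (!length(idx))
    return(data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0), width = numeric(0)))
  prom <- peak_prominence(x, idx)
  keep <- prom >= min_prominence
  idx <- idx[keep]; prom <- prom[keep]
  if (!length(idx))
    return(data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0), width = numeric(0)))
  wid <- peak_width(x, idx, prom)
  keep <- wid >= min_width
  data.frame(index = idx[keep], height = x[idx[keep]],
             prominence = prom[keep], width = wid[keep])
}

# Local minima of x are peaks of -x.
find_troughs <- function(x, min_prominence = 0, min_width = 0) {
  out <- find_peaks(-x, min_prominence = min_prominence,
                    min_width = min_width)
  out$height <- -out$height
  out
}
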