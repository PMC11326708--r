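# Tube boundary detection.
#
# A pack image holds ~6 horizontal tubes separated by thin dark margins.
# Two redundant detectors find these margins: (1) Canny edge detection
# followed by a Hough-style search for long, nearly horizontal line
# segments; (2) vertical densitometry, pairing brightness minima of two
# vertical strip profiles. The larger acceptable set wins.

RT_MIN_LINE_LENGTH <- 300   # px; only inter-tube margins are this long
RT_MAX_SLOPE <- 5           # px rise across the full 1160 px width
RT_MIN_SEPARATION <- 20     # px between accepted boundary lines
RT_LINE_GAP <- 3            # px gap bridged inside a Hough segment
RT_HOUGH_MIN_VOTES <- 10    # minimum true edge pixels on a segment
RT_MIN_TUBE_HEIGHT <- 15    # px; shorter regions are slivers, discarded

gaussian_blur <- function(m, sigma = 1) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_reflect <- function(v, r) c(rev(v[2:(r + 1)]), v, rev(v[(length(v) - r):(length(v) - 1)]))
  conv1 <- function(v) {
    vp <- pad_reflect(v, r)
    stats::filter(vp, k, sides = 2)[(r + 1):(r + length(v))]
  }
  m2 <- apply(m, 2L, conv1)     # along rows (y)
  t(apply(m2, 1L, conv1))       # along columns (x)
}

sobel_gradients <- function(m) {
  shift <- function(m, dy, dx) {
    nr <- nrow(m); nc <- ncol(m)
    ys <- pmin(pmax(seq_len(nr) + dy, 1L), nr)
    xs <- pmin(pmax(seq_len(nc) + dx, 1L), nc)
    m[ys, xs, drop = FALSE]
  }
  gx <- (shift(m, -1, 1) + 2 * shift(m, 0, 1) + shift(m, 1, 1) -
         shift(m, -1, -1) - 2 * shift(m, 0, -1) - shift(m, 1, -1)) / 4
  gy <- (shift(m, 1, -1) + 2 * shift(m, 1, 0) + shift(m, 1, 1) -
         shift(m, -1, -1) - 2 * shift(m, -1, 0) - shift(m, -1, 1)) / 4
  list(gx = gx, gy = gy)
}

#' Canny edge detection
#'
#' Gaussian presmoothing, Sobel gradients, non-maximum suppression along
#' the quantized gradient direction, then hysteresis thresholding: weak
#' edge pixels (magnitude >= `low`) are kept only when connected to a
#' strong pixel (magnitude >= `high`). Thresholds are on the 0-255
#' brightness scale; the defaults (1, 25) keep faint tube margins while
#' anchoring them to genuinely dark boundary pixels.
#'
#' @param img a `race_tube_image`.
#' @param low,high hysteresis thresholds on gradient magnitude.
#' @param sigma Gaussian presmoothing standard deviation in px.
#' @return logical matrix, same shape as the image; `TRUE` at edges.
#' @export
detect_canny_edges <- function(img, low = 1, high = 25, sigma = 1) {
  stopifnot(inherits(img, "race_tube_image"))
  m <- gaussian_blur(img$pixels, sigma)
  g <- sobel_gradients(m)
  mag <- sqrt(g$gx^2 + g$gy^2)
  if (max(mag) == 0) return(matrix(FALSE, nrow(m), ncol(m)))

  # non-maximum suppression: compare against the two neighbours along the
  # gradient direction, quantized to 0/45/90/135 degrees
  ang <- atan2(g$gy, g$gx)            # gradient direction
  q <- (round(ang / (pi / 4)) %% 4)   # 0: horiz grad, 2: vert grad
  nr <- nrow(m); nc <- ncol(m)
  off <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  nms <- matrix(FALSE, nr, nc)
  for (d in 0:3) {
    o <- off[[as.character(d)]]
    sh <- function(dy, dx) {
      ys <- pmin(pmax(seq_len(nr) + dy, 1L), nr)
      xs <- pmin(pmax(seq_len(nc) + dx, 1L), nc)
      mag[ys, xs, drop = FALSE]
    }
    sel <- q == d
    nms[sel] <- mag[sel] >= sh(o[1], o[2])[sel] &
                mag[sel] >= sh(-o[1], -o[2])[sel]
  }
  weak <- nms & mag >= low
  strong <- nms & mag >= high
  if (!any(strong)) return(matrix(FALSE, nr, nc))

  # hysteresis via connected-component labelling of the weak mask
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(weak))))
  lab <- t(lab)
  keep <- unique(lab[strong])
  keep <- keep[keep > 0]
  weak & (lab %in% keep)
}

new_boundary_line <- function(y_left, y_right, method) {
  data.frame(y_left = y_left, y_right = y_right, method = method,
             stringsAsFactors = FALSE)
}

line_mean_y <- function(lines) (lines$y_left + lines$y_right) / 2

# Longest run of TRUE allowing internal gaps of at most `gap` FALSEs;
# also returns the number of TRUE pixels inside that run.
longest_run <- function(v, gap) {
  idx <- which(v)
  if (!length(idx)) return(c(len = 0, votes = 0))
  d <- diff(idx)
  breaks <- which(d > gap + 1L)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(idx))
  lens <- idx[ends] - idx[starts] + 1L
  k <- which.max(lens)
  c(len = lens[k], votes = ends[k] - starts[k] + 1L)
}

#' Boundary lines from a Hough-style segment search
#'
#' Deterministic exhaustive search over low-slope lines: for every
#' intercept row and integer rise across the image width (|rise| <=
#' `max_slope`), the edge pixels within 1 px of the line are collected and
#' the longest run with gaps <= `line_gap` is measured. Lines whose
#' longest segment reaches `min_line_length` are accepted, extended to the
#' full image width, and deduplicated so accepted lines are at least
#' `min_separation` px apart (keeping the strongest).
#'
#' @param edges logical edge mask from [detect_canny_edges()].
#' @param min_line_length minimum segment length in px.
#' @param max_slope maximum |rise| in px across the full width.
#' @param line_gap largest gap bridged within a segment, px.
#' @param min_votes minimum count of actual edge pixels in the segment.
#' @param min_separation merge radius between accepted lines, px.
#' @return data.frame of boundary lines (`y_left`, `y_right`, `method`),
#'   sorted by mean row; possibly zero rows.
#' @export
boundaries_from_hough <- function(edges,
                                  min_line_length = RT_MIN_LINE_LENGTH,
                                  max_slope = RT_MAX_SLOPE,
                                  line_gap = RT_LINE_GAP,
                                  min_votes = RT_HOUGH_MIN_VOTES,
                                  min_separation = RT_MIN_SEPARATION) {
  nr <- nrow(edges); nc <- ncol(edges)
  cand <- list()
  for (s in seq.int(-max_slope, max_slope)) {
    off <- as.integer(round(s * (seq_len(nc) - 1L) / (nc - 1L)))
    # M[y, x] = any edge within 1 px of row y + off[x]
    M <- matrix(FALSE, nr, nc)
    for (o in unique(off)) {
      xs <- which(off == o)
      for (dd in -1:1) {
        ys_dst <- seq_len(nr)
        ys_src <- ys_dst + o + dd
        ok <- ys_src >= 1L & ys_src <= nr
        M[ys_dst[ok], xs] <- M[ys_dst[ok], xs] | edges[ys_src[ok], xs, drop = FALSE]
      }
    }
    for (y0 in seq_len(nr)) {
      r <- longest_run(M[y0, ], line_gap)
      if (r["len"] >= min_line_length && r["votes"] >= min_votes) {
        cand[[length(cand) + 1L]] <-
          c(y_left = y0, y_right = y0 + s, len = r["len"])
      }
    }
  }
  if (!length(cand))
    return(new_boundary_line(numeric(0), numeric(0), character(0)))
  cand <- do.call(rbind, cand)
  # a dark margin yields a Canny edge on each flank; cluster candidates
  # within min_separation (seeded by the strongest) and take the
  # vote-weighted mean line of each cluster so it lands on the margin
  # centre rather than one flank
  ord <- order(-cand[, "len.len"], cand[, "y_left"])
  my_all <- (cand[, "y_left"] + cand[, "y_right"]) / 2
  centres <- numeric(0)
  assign_to <- rep(NA_integer_, nrow(cand))
  for (i in ord) {
    d <- abs(centres - my_all[i])
    if (length(d) && min(d) < min_separation) {
      assign_to[i] <- which.min(d)
    } else {
      centres <- c(centres, my_all[i])
      assign_to[i] <- length(centres)
    }
  }
  kept <- t(vapply(seq_along(centres), function(k) {
    sel <- assign_to == k
    w <- cand[sel, "len.len"]
    c(sum(cand[sel, "y_left"] * w) / sum(w),
      sum(cand[sel, "y_right"] * w) / sum(w))
  }, numeric(2)))
  out <- new_boundary_line(pmin(pmax(kept[, 1], 1), nr),
                           pmin(pmax(kept[, 2], 1), nr),
                           "canny_hough")
  out[order(line_mean_y(out)), , drop = FALSE]
}

#' Boundary lines from vertical densitometry
#'
#' Takes the mean brightness over a horizontal window at every image row,
#' once in a strip at the left edge and once in a strip at the image
#' centre. Local minima (tube margins are dark) of sufficient prominence
#' are detected in each profile, paired between the strips when the
#' implied slope is acceptably low, and each pair is extended to a full
#' width line through the two strip centres.
#'
#' @param img a `race_tube_image`.
#' @param strip_width width of each sampling strip in px.
#' @param prominence minimum trough prominence in brightness units.
#' @param max_slope maximum |rise| across the full width, px.
#' @return data.frame of boundary lines sorted by mean row.
#' @export
boundaries_from_vertical_density <- function(img, strip_width = 58,
                                             prominence = 5,
                                             max_slope = RT_MAX_SLOPE) {
  stopifnot(inherits(img, "race_tube_image"))
  px <- img$pixels
  nc <- ncol(px)
  xl <- seq_len(strip_width)
  xc <- seq.int(round(nc / 2 - strip_width / 2) + 1L,
                length.out = strip_width)
  prof_l <- rowMeans(px[, xl, drop = FALSE])
  prof_c <- rowMeans(px[, xc, drop = FALSE])
  min_l <- find_troughs(prof_l, min_prominence = prominence)$index
  min_c <- find_troughs(prof_c, min_prominence = prominence)$index
  if (!length(min_l) || !length(min_c))
    return(new_boundary_line(numeric(0), numeric(0), character(0)))
  cl <- mean(xl); cc <- mean(xc)             # strip centres (columns)
  dy_max <- max_slope * (cc - cl) / (nc - 1) + 0.5
  # greedy unique pairing by |dy|
  pairs <- expand.grid(l = seq_along(min_l), c = seq_along(min_c))
  pairs$dy <- abs(min_l[pairs$l] - min_c[pairs$c])
  pairs <- pairs[pairs$dy <= dy_max, , drop = FALSE]
  pairs <- pairs[order(pairs$dy), , drop = FALSE]
  used_l <- used_c <- logical(0)
  yl <- yr <- numeric(0)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$l[k]; j <- pairs$c[k]
    if (i %in% used_l || j %in% used_c) next
    used_l <- c(used_l, i); used_c <- c(used_c, j)
    a <- min_l[i]; b <- min_c[j]              # rows (1-based)
    slope <- (b - a) / (cc - cl)
    yl <- c(yl, a + slope * (1 - cl))
    yr <- c(yr, a + slope * (nc - cl))
  }
  yl <- pmin(pmax(yl, 1), nrow(px))
  yr <- pmin(pmax(yr, 1), nrow(px))
  out <- new_boundary_line(yl, yr, "vertical_density")
  out[order(line_mean_y(out)), , drop = FALSE]
}

#' Select the larger acceptable boundary set and build tube regions
#'
#' Both detectors run on every image; the larger candidate list is kept
#' (ties prefer the Canny/Hough list). User overrides are applied after
#' selection: `add` inserts horizontal lines at the given rows, `remove`
#' drops the nearest detected line within 10 px. The image's top and
#' bottom edges act as implicit boundaries; regions shorter than
#' `min_tube_height` are discarded as slivers.
#'
#' @param a,b candidate boundary data.frames (Canny/Hough and vertical
#'   density, in that order).
#' @param add,remove numeric vectors of rows (1-based) for overrides.
#' @param min_separation dedup radius in px.
#' @param min_tube_height minimum tube region height in px.
#' @param img_height image height in px.
#' @return a `tube_boundary_set`: list with `lines` (data.frame) and
#'   `tubes` (data.frame with `index`, `top_left`, `top_right`,
#'   `bottom_left`, `bottom_right`), tubes numbered top-down.
#' @export
select_boundaries <- function(a, b, add = NULL, remove = NULL,
                              min_separation = RT_MIN_SEPARATION,
                              min_tube_height = RT_MIN_TUBE_HEIGHT,
                              img_height = RT_HEIGHT) {
  lines <- if (nrow(b) > nrow(a)) b else a
  if (length(add)) {
    lines <- rbind(lines, new_boundary_line(add, add, "user"))
  }
  lines <- lines[order(line_mean_y(lines)), , drop = FALSE]
  # dedup: enforce min_separation top-down
  if (nrow(lines) > 1) {
    keep <- rep(TRUE, nrow(lines))
    last <- line_mean_y(lines)[1]
    for (i in seq_len(nrow(lines))[-1]) {
      my <- line_mean_y(lines)[i]
      if (my - last < min_separation) keep[i] <- FALSE else last <- my
    }
    lines <- lines[keep, , drop = FALSE]
  }
  if (length(remove)) {
    for (y in remove) {
      d <- abs(line_mean_y(lines) - y)
      if (length(d) && min(d) <= 10) lines <- lines[-which.min(d), , drop = FALSE]
    }
  }
  rownames(lines) <- NULL
  # implicit outer boundaries
  ext <- rbind(new_boundary_line(1, 1, "edge"),
               lines,
               new_boundary_line(img_height, img_height, "edge"))
  tubes <- data.frame(index = integer(0), top_left = numeric(0),
                      top_right = numeric(0), bottom_left = numeric(0),
                      bottom_right = numeric(0),
                      top_method = character(0), bottom_method = character(0))
  for (i in seq_len(nrow(ext) - 1)) {
    h <- line_mean_y(ext[i + 1, , drop = FALSE]) -
         line_mean_y(ext[i, , drop = FALSE])
    if (h >= min_tube_height) {
      tubes <- rbind(tubes, data.frame(
        index = nrow(tubes) + 1L,
        top_left = ext$y_left[i], top_right = ext$y_right[i],
        bottom_left = ext$y_left[i + 1], bottom_right = ext$y_right[i + 1],
        top_method = ext$method[i], bottom_method = ext$method[i + 1]))
    }
  }
  if (nrow(tubes) < 2)
    rt_error("fewer than 2 tube regions found; check the image or supply boundary overrides",
             "rt_no_tubes_error")
  structure(list(lines = lines, tubes = tubes), class = "tube_boundary_set")
}

#' Detect tube boundaries in a normalized pack image
#'
#' Runs both boundary detectors and selects the larger acceptable set;
#' see [select_boundaries()].
#'
#' @inheritParams detect_canny_edges
#' @inheritParams select_boundaries
#' @param ... passed to [select_boundaries()].
#' @return a `tube_boundary_set`.
#' @export
detect_tube_boundaries <- function(img, add = NULL, remove = NULL, ...) {
  edges <- detect_canny_edges(img)
  a <- boundaries_from_hough(edges)
  b <- boundaries_from_vertical_density(img)
  select_boundaries(a, b, add = add, remove = remove, ...)
}

#' @export
print.tube_boundary_set <- function(x, ...) {
  cat(sprintf("tube_boundary_set: %d boundary lines, %d tubes\n",
              nrow(x$lines), nrow(x$tubes)))
  invisible(x)
}
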