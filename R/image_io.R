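#' @section Canonical frame:
#' All analysis runs on a fixed 1160x400 greyscale frame. 1160x400 matches
#' the aspect ratio of the straight portion of a six-pack of race tubes;
#' moderate stretching of a scan does not move period estimates by more than
#' the measurement error, so a single canonical size keeps every downstream
#' parameter (window widths, line lengths, separations) in one coordinate
#' system.
#' @name image-normalization
#' @keywords internal
NULL

RT_WIDTH <- 1160L
RT_HEIGHT <- 400L

# ITU-R BT.601 luminance weights for RGB -> grey
RT_LUMA <- c(0.299, 0.587, 0.114)

#' Convert a colour pixel array to a single greyscale channel
#'
#' Channels are interpreted as: 1 = grey, 2 = grey + alpha, 3 = RGB,
#' 4 = RGBA. RGB is reduced with the ITU-R BT.601 luminance weights
#' (0.299, 0.587, 0.114); alpha channels are dropped, not composited,
#' since flatbed scans carry no meaningful transparency.
#'
#' @param pixels a numeric matrix (already grey) or a 3-d array
#'   `[row, col, channel]` with 1-4 channels.
#' @return a numeric matrix of the same height/width, one value per pixel.
#' @export
#' @examples
#' px <- array(c(255, 0, 0), c(1, 1, 3))
#' to_greyscale(px)  # 0.299 * 255
to_greyscale <- function(pixels) {
  if (is.matrix(pixels)) return(pixels)
  if (length(dim(pixels)) != 3L)
    rt_error("pixel array must be a matrix or 3-d array", "rt_format_error")
  nc <- dim(pixels)[3L]
  ch <- function(k) array(pixels[, , k], dim(pixels)[1:2])
  if (nc %in% c(1L, 2L)) return(ch(1L))   # grey (+ alpha, dropped)
  if (nc %in% c(3L, 4L)) {
    return(RT_LUMA[1L] * ch(1L) + RT_LUMA[2L] * ch(2L) + RT_LUMA[3L] * ch(3L))
  }
  rt_error(sprintf("unsupported channel count: %d", nc), "rt_format_error")
}

# Keys bicubic kernel, a = -0.5 (the common convention in imaging libraries)
bicubic_kernel <- function(t) {
  a <- -0.5
  t <- abs(t)
  w <- numeric(length(t))
  i1 <- t <= 1
  i2 <- t > 1 & t < 2
  w[i1] <- (a + 2) * t[i1]^3 - (a + 3) * t[i1]^2 + 1
  w[i2] <- a * t[i2]^3 - 5 * a * t[i2]^2 + 8 * a * t[i2] - 4 * a
  w
}

# Row-interpolation weight matrix (n_out x n_in) for separable bicubic
# resampling with centre-aligned sampling. When downscaling, the kernel
# support is widened by the scale factor (area-averaging antialias); at
# scale 1 this reduces to the identity.
bicubic_weight_matrix <- function(n_out, n_in) {
  scale <- n_in / n_out
  fs <- max(1, scale)             # filter scale (antialias when shrinking)
  support <- 2 * fs
  W <- matrix(0, n_out, n_in)
  centers <- (seq_len(n_out) - 0.5) * scale - 0.5   # 0-based source coords
  for (i in seq_len(n_out)) {
    c0 <- centers[i]
    lo <- ceiling(c0 - support)
    hi <- floor(c0 + support)
    j <- lo:hi
    w <- bicubic_kernel((j - c0) / fs)
    j <- pmin(pmax(j, 0L), n_in - 1L)  # replicate edges
    w <- w / sum(w)
    for (k in seq_along(j)) W[i, j[k] + 1L] <- W[i, j[k] + 1L] + w[k]
  }
  W
}

#' Bicubic resize of a greyscale matrix
#'
#' Separable bicubic resampling (Keys kernel, a = -0.5), centre-aligned,
#' with edge replication. When downscaling, the kernel is scaled to the
#' sampling step so high-frequency content is averaged rather than
#' aliased. Resizing to the native size is an exact identity.
#'
#' @param m numeric matrix (rows = y, cols = x).
#' @param height,width output dimensions.
#' @return numeric matrix `height` x `width`.
#' @export
resize_bicubic <- function(m, height = RT_HEIGHT, width = RT_WIDTH) {
  if (nrow(m) == 0L || ncol(m) == 0L)
    rt_error("cannot resize a zero-area image", "rt_degenerate_input")
  Wv <- if (nrow(m) == height) NULL else bicubic_weight_matrix(height, nrow(m))
  Wh <- if (ncol(m) == width) NULL else bicubic_weight_matrix(width, ncol(m))
  out <- m
  if (!is.null(Wv)) out <- Wv %*% out
  if (!is.null(Wh)) out <- out %*% t(Wh)
  out
}

apply_orientation <- function(m, orientation) {
  switch(orientation,
    none   = m,
    rot90  = t(m[nrow(m):1, , drop = FALSE]),          # 90 deg clockwise
    rot180 = m[nrow(m):1, ncol(m):1, drop = FALSE],
    rot270 = t(m)[ncol(m):1, , drop = FALSE],
    flip_h = m[, ncol(m):1, drop = FALSE],
    flip_v = m[nrow(m):1, , drop = FALSE],
    rt_error(sprintf("unknown orientation '%s'", orientation),
             "rt_format_error")
  )
}

new_race_tube_image <- function(pixels, source_path = "", pack_name = "",
                                orientation_applied = "none") {
  structure(
    list(pixels = pixels, source_path = source_path, pack_name = pack_name,
         orientation_applied = orientation_applied),
    class = "race_tube_image"
  )
}

#' Normalize a pixel matrix or array into a race-tube image
#'
#' Applies the requested orientation, converts colour to greyscale,
#' resizes to the canonical 1160x400 frame with bicubic interpolation,
#' and quantizes to integers in \[0, 255\] (round half to even).
#'
#' @param pixels numeric matrix or 3-d array on a 0-255 scale.
#' @param orientation one of `"none"`, `"rot90"`, `"rot180"`, `"rot270"`,
#'   `"flip_h"`, `"flip_v"`, applied before resizing so that growth runs
#'   left to right (inoculation end at x = 1).
#' @param source_path,pack_name provenance strings carried on the object.
#' @return a `race_tube_image`: list with `pixels` (400x1160 integer
#'   matrix), `source_path`, `pack_name`, `orientation_applied`.
#' @export
as_race_tube <- function(pixels, orientation = "none", source_path = "",
                         pack_name = "") {
  m <- to_greyscale(pixels)
  if (nrow(m) == 0L || ncol(m) == 0L)
    rt_error("zero-area image", "rt_degenerate_input")
  m <- apply_orientation(m, orientation)
  m <- resize_bicubic(m, RT_HEIGHT, RT_WIDTH)
  m <- round(m)                      # round() is round-half-to-even in R
  m[m < 0] <- 0
  m[m > 255] <- 255
  storage.mode(m) <- "integer"
  new_race_tube_image(m, source_path, pack_name, orientation)
}

#' Load and normalize a scanned race-tube pack image
#'
#' Reads a raster image (PNG, TIFF or JPEG; the formats the underlying
#' reader supports), reduces colour to a single brightness channel,
#' applies an explicit orientation, and resizes to the canonical
#' 1160x400 greyscale frame by bicubic interpolation.
#'
#' @param path image file path.
#' @param orientation see [as_race_tube()]. Orientation is explicit, not
#'   auto-detected: the scan must end up with growth left to right.
#' @param pack_name user-facing name for the pack; defaults to the file
#'   stem.
#' @return a `race_tube_image`.
#' @export
load_race_tube <- function(path, orientation = "none", pack_name = NULL) {
  if (!file.exists(path))
    rt_error(sprintf("file not found: %s", path), "rt_format_error")
  img <- tryCatch(EBImage::readImage(path), error = function(e)
    rt_error(sprintf("cannot read '%s' as an image: %s", path,
                     conditionMessage(e)), "rt_format_error"))
  arr <- EBImage::imageData(img)    # dims: [x, y] or [x, y, channel]
  arr <- if (length(dim(arr)) == 2L) t(arr) else aperm(arr, c(2L, 1L, 3L))
  as_race_tube(arr * 255,
               orientation = orientation,
               source_path = path,
               pack_name = pack_name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write the normalized greyscale image as an 8-bit PNG
#'
#' @param img a `race_tube_image`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_greyscale_png <- function(img, path) {
  stopifnot(inherits(img, "race_tube_image"))
  png::writePNG(img$pixels / 255, path)
  invisible(path)
}

#' @export
print.race_tube_image <- function(x, ...) {
  cat(sprintf("race_tube_image '%s' (%dx%d, orientation %s)\n",
              x$pack_name, ncol(x$pixels), nrow(x$pixels),
              x$orientation_applied))
  cat(sprintf("  brightness range [%d, %d], source: %s\n",
              min(x$pixels), max(x$pixels),
              if (nzchar(x$source_path)) x$source_path else "<in memory>"))
  invisible(x)
}
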