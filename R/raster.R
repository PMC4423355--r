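# Raster conventions used throughout the package:
#   * colour images are numeric arrays [row, col, 3] with values in 0..255
#     (row 1 = top of the image, column 1 = left; "origin upper-left")
#   * greyscale images are numeric matrices [row, col] in 0..255
#   * binary masks are integer/logical matrices (1 = embryo)
# x refers to the column (rightward), y to the row (downward).

#' Read an 8-bit RGB PNG as a 0--255 raster array
#'
#' @param path Path to a PNG file.
#' @return Numeric array `[row, col, 3]` with values in `[0, 255]`.
#' @export
read_raster_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE] # drop alpha
  round(a * 255)
}

#' Write a 0--255 raster array as an 8-bit RGB PNG
#'
#' @param img Numeric array `[row, col, 3]` or matrix, values in `[0, 255]`.
#' @param path Output path; parent directories are created.
#' @return `path`, invisibly.
#' @export
write_raster_png <- function(img, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (is.matrix(img)) img <- array(rep(img, 3L), c(dim(img), 3L))
  img <- pmin(pmax(img, 0), 255)
  png::writePNG(img / 255, path)
  invisible(path)
}

# Convert an RGB raster to a single luminance matrix (plain channel mean).
raster_grey <- function(img) {
  if (is.matrix(img)) return(img)
  (img[, , 1] + img[, , 2] + img[, , 3]) / 3
}

# Clip to the 8-bit range without rounding.
clip255 <- function(x) pmin(pmax(x, 0), 255)

# Round half away from zero (R's round() is round-half-even).
round_half_up <- function(x) floor(x + 0.5)

#' Rotate a raster about a centre point
#'
#' Rotates image content counter-clockwise (as seen on screen, with the y
#' axis pointing down) by `angle_deg` about `center` using inverse mapping.
#' The canvas keeps its dimensions; pixels mapping outside the source are
#' filled with `fill`.
#'
#' @param img Matrix or `[row, col, 3]` array.
#' @param angle_deg Rotation angle in degrees, counter-clockwise on screen.
#' @param center `(x, y)` pixel coordinates of the rotation centre; defaults
#'   to the canvas centre.
#' @param interp `"bilinear"` (images) or `"nearest"` (masks).
#' @param fill Fill value for out-of-canvas source pixels.
#' @return Raster of the same dimensions.
#' @export
rotate_raster <- function(img, angle_deg, center = NULL,
                          interp = c("bilinear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  d <- dim(img)
  h <- d[1]; w <- d[2]
  if (is.null(center)) center <- c((w + 1) / 2, (h + 1) / 2)
  th <- angle_deg * pi / 180
  # Forward model: screen-CCW rotation maps (u,v) -> (u cos + v sin, -u sin + v cos)
  # relative to the centre. Inverse mapping applies the transpose.
  xo <- rep(seq_len(w), each = h) - center[1]
  yo <- rep(seq_len(h), times = w) - center[2]
  xs <- center[1] + xo * cos(th) - yo * sin(th)
  ys <- center[2] + xo * sin(th) + yo * cos(th)

  sample_plane <- function(m) {
    out <- matrix(fill, h, w)
    if (interp == "nearest") {
      xi <- round(xs); yi <- round(ys)
      ok <- xi >= 1 & xi <= w & yi >= 1 & yi <= h
      out[ok] <- m[cbind(yi[ok], xi[ok])]
    } else {
      x0 <- floor(xs); y0 <- floor(ys)
      fx <- xs - x0; fy <- ys - y0
      ok <- x0 >= 1 & x0 + 1 <= w & y0 >= 1 & y0 + 1 <= h
      i00 <- cbind(y0[ok], x0[ok]);     i01 <- cbind(y0[ok], x0[ok] + 1)
      i10 <- cbind(y0[ok] + 1, x0[ok]); i11 <- cbind(y0[ok] + 1, x0[ok] + 1)
      out[ok] <- m[i00] * (1 - fx[ok]) * (1 - fy[ok]) +
                 m[i01] * fx[ok] * (1 - fy[ok]) +
                 m[i10] * (1 - fx[ok]) * fy[ok] +
                 m[i11] * fx[ok] * fy[ok]
    }
    out
  }

  if (is.matrix(img)) return(sample_plane(img))
  out <- array(0, d)
  for (k in seq_len(d[3])) out[, , k] <- sample_plane(img[, , k])
  out
}

# Mirror a raster left<->right.
mirror_raster <- function(img) {
  if (is.matrix(img)) return(img[, rev(seq_len(ncol(img))), drop = FALSE])
  img[, rev(seq_len(ncol(img))), , drop = FALSE]
}

# Crop rows r1:r2 and columns c1:c2, clamped to the canvas.
crop_raster <- function(img, r1, r2, c1, c2) {
  d <- dim(img)
  r1 <- max(1L, r1); r2 <- min(d[1], r2)
  c1 <- max(1L, c1); c2 <- min(d[2], c2)
  if (is.matrix(img)) img[r1:r2, c1:c2, drop = FALSE] else
    img[r1:r2, c1:c2, , drop = FALSE]
}

# 3x3 maximum filter via shifted copies (used for local-maximum detection).
dilate3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  out <- matrix(-Inf, h, w)
  for (dr in 0:2) for (dc in 0:2)
    out <- pmax(out, pad[(1 + dr):(h + dr), (1 + dc):(w + dc)])
  out
}

# Moving-average smoothing of a numeric vector with edge truncation
# (window shrinks near the ends rather than padding).
moving_average <- function(x, width) {
  if (width <= 1L || length(x) < 2L) return(x)
  n <- length(x)
  half <- floor(width / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
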