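# Midline: locate the lateral midline of the aligned embryo as a natural
# cubic spline through five equidistant knots (initialised from the mask
# skeleton) and define the extraction strip spanning 10% of mask height.

#' Extract the skeleton midline path of an embryo mask
#'
#' Thins the mask to its morphological skeleton (Zhang-Suen), keeps the
#' single longest path (graph diameter of the skeleton, 8-connected), and
#' returns it ordered left to right.
#'
#' @param mask An [embryo_mask].
#' @return Data frame with columns `x`, `y`: the ordered pixel path.
#' @export
skeleton_midline <- function(mask) {
  stopifnot(inherits(mask, "embryo_mask"))
  m <- mask$mask
  storage.mode(m) <- "integer"
  sk <- thin_binary(m)
  pts <- which(sk > 0, arr.ind = TRUE)
  if (nrow(pts) < 5)
    stop("degenerate skeleton: mask reduces to ", nrow(pts),
         " pixel(s); cannot define a midline")
  path <- skeleton_longest_path(sk, pts)
  if (nrow(path) < 0.6 * nrow(pts))
    stop("ambiguous skeleton: no dominant path (branched skeleton)")
  if (diff(range(path$x)) < 2 * diff(range(path$y)))
    stop("degenerate skeleton: path is not predominantly horizontal")
  if (path$x[1] > path$x[nrow(path)]) path <- path[rev(seq_len(nrow(path))), ]
  rownames(path) <- NULL
  path
}

# Graph diameter of the skeleton pixel graph via double BFS.
skeleton_longest_path <- function(sk, pts) {
  h <- nrow(sk); w <- ncol(sk)
  id <- matrix(0L, h, w)
  id[pts] <- seq_len(nrow(pts))
  offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  nbrs <- function(i) {
    r <- pts[i, 1] + offs[, 1]; c <- pts[i, 2] + offs[, 2]
    ok <- r >= 1 & r <= h & c >= 1 & c <= w
    v <- id[cbind(r[ok], c[ok])]
    v[v > 0]
  }
  bfs <- function(start) {
    dist <- rep(NA_integer_, nrow(pts)); prev <- rep(0L, nrow(pts))
    dist[start] <- 0L
    queue <- start
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in nbrs(cur)) if (is.na(dist[nb])) {
        dist[nb] <- dist[cur] + 1L; prev[nb] <- cur
        queue <- c(queue, nb)
      }
    }
    list(dist = dist, prev = prev)
  }
  b1 <- bfs(1L)
  e1 <- which.max(b1$dist)
  b2 <- bfs(e1)
  e2 <- which.max(b2$dist)
  path_ids <- integer(0)
  cur <- e2
  while (cur != 0L) { path_ids <- c(path_ids, cur); cur <- b2$prev[cur] }
  data.frame(x = pts[path_ids, 2], y = pts[path_ids, 1])
}

#' Place five equidistant midline knots
#'
#' Knot x positions partition the mask's horizontal span into four equal
#' intervals; knot y values are read from the skeleton path after smoothing
#' with a 15-px moving average (nearest path column; the path rarely
#' reaches the embryo poles, where the nearest available column is used).
#' A manual `override` (5 knots) replaces the computed knots verbatim,
#' mirroring curator adjustment.
#'
#' @param path Skeleton path from [skeleton_midline()].
#' @param mask The [embryo_mask] the path came from.
#' @param override Optional data frame / matrix of 5 `(x, y)` knots.
#' @param smooth_px Moving-average window for path smoothing (default 15).
#' @return A `midline_spline`: list with `knots` (5-row data frame) and
#'   `fun` (natural cubic spline interpolant, parameterised by x).
#' @export
place_knots <- function(path, mask, override = NULL, smooth_px = 15) {
  if (!is.null(override)) {
    ov <- as.data.frame(override)
    names(ov) <- c("x", "y")
    return(midline_spline(ov))
  }
  stopifnot(inherits(mask, "embryo_mask"), nrow(path) >= 5)
  x_min <- mask$bbox[["c1"]]; x_max <- mask$bbox[["c2"]]
  kx <- seq(x_min, x_max, length.out = 5)
  ord <- order(path$x)
  yx <- tapply(path$y[ord], path$x[ord], mean)
  xs <- as.numeric(names(yx))
  ys <- moving_average(as.numeric(yx), smooth_px)
  ky <- stats::approx(xs, ys, xout = kx, rule = 2)$y
  midline_spline(data.frame(x = kx, y = ky))
}

#' Midline spline through five knots
#'
#' @param knots Data frame with 5 rows, columns `x`, `y`; x strictly
#'   increasing.
#' @return A `midline_spline` object.
#' @export
midline_spline <- function(knots) {
  knots <- as.data.frame(knots)
  if (nrow(knots) != 5L) stop("a midline spline needs exactly 5 knots, got ",
                              nrow(knots))
  if (is.unsorted(knots$x, strictly = TRUE))
    stop("knot x values must be strictly increasing")
  fun <- stats::splinefun(knots$x, knots$y, method = "natural")
  structure(list(knots = knots, fun = fun), class = "midline_spline")
}

#' Build the 10%-of-embryo-height extraction strip
#'
#' The strip follows the midline spline; its height is 10% of the embryo
#' mask height, rounded half-up to a whole pixel.
#'
#' @param spline A [midline_spline].
#' @param mask The [embryo_mask].
#' @param strip_fraction Fraction of mask height (default 0.10).
#' @return A `strip_band`: list with `spline`, `height_px`,
#'   `mask_height_px`.
#' @export
make_strip <- function(spline, mask, strip_fraction = 0.10) {
  stopifnot(inherits(spline, "midline_spline"), inherits(mask, "embryo_mask"))
  if (mask$height_px <= 0) stop("mask height must be positive")
  h <- round_half_up(strip_fraction * mask$height_px)
  structure(list(spline = spline, height_px = as.integer(h),
                 mask_height_px = mask$height_px),
            class = "strip_band")
}

# Pixel coordinates of the strip column at integer x: `height_px` samples
# at unit spacing along the normal to the local spline tangent.
strip_column <- function(strip, x) {
  y <- strip$spline$fun(x)
  dy <- strip$spline$fun(x, deriv = 1)
  nrm <- sqrt(1 + dy^2)
  t <- seq_len(strip$height_px) - (strip$height_px + 1) / 2
  list(x = x - t * dy / nrm, y = y + t / nrm)
}

#' Render strip overlay images
#'
#' Paints the strip outline (top edge, bottom edge, and end columns) onto a
#' base raster: on the binary mask for the `_band` image, on the
#' bright-field for the `_stband` image.
#'
#' @param base Raster to draw on (mask matrix or RGB array).
#' @param strip A [strip_band].
#' @param color RGB triplet for the outline (default green).
#' @return RGB raster with the outline painted.
#' @export
render_strip_overlay <- function(base, strip, color = c(0, 255, 0)) {
  if (is.matrix(base)) base <- array(rep(base * if (max(base) <= 1) 255 else 1,
                                         3), c(dim(base), 3))
  d <- dim(base)
  xs <- seq(min(strip$spline$knots$x), max(strip$spline$knots$x))
  for (x in xs) {
    col <- strip_column(strip, x)
    pick <- if (x == xs[1] || x == xs[length(xs)])
      seq_along(col$x) else c(1L, length(col$x))
    r <- round(col$y[pick]); c <- round(col$x[pick])
    ok <- r >= 1 & r <= d[1] & c >= 1 & c <= d[2]
    for (k in 1:3) base[cbind(r[ok], c[ok], k)] <- color[k]
  }
  base
}
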