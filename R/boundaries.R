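# Expression-domain boundaries: detect monotone rises/falls in an intensity
# profile and fit each with a clamped cubic spline (zero first derivative at
# both ends) through three control points (start, mid, end). The boundary
# position is the half-amplitude (mid) point, its width the start-to-end
# span -- the standard convention in the gap-gene literature.

#' Clamped cubic spline through three control points
#'
#' Two cubic Hermite segments over `[x1, x2]` and `[x2, x3]` with zero
#' slope at `x1` and `x3`; the interior slope at `x2` is the unique value
#' making the second derivative continuous, i.e. the clamped cubic
#' interpolation spline with end derivatives 0. The function extends as a
#' constant (slope 0) beyond `[x1, x3]`.
#'
#' @param x Numeric length-3, strictly increasing control-point abscissae.
#' @param y Numeric length-3 control-point ordinates (intensity space).
#' @return A function `f(t, deriv = 0)` evaluating the spline or its first
#'   derivative.
#' @export
clamped_spline <- function(x, y) {
  stopifnot(length(x) == 3L, length(y) == 3L, x[1] < x[2], x[2] < x[3])
  h1 <- x[2] - x[1]; h2 <- x[3] - x[2]
  d1 <- (y[2] - y[1]) / h1; d2 <- (y[3] - y[2]) / h2
  # C2 continuity at x2 with f'(x1) = f'(x3) = 0
  m2 <- 1.5 * (d1 / h1 + d2 / h2) / (1 / h1 + 1 / h2)
  hermite <- function(t, xa, xb, ya, yb, ma, mb, deriv) {
    h <- xb - xa; u <- (t - xa) / h
    if (deriv == 0) {
      (2 * u^3 - 3 * u^2 + 1) * ya + (u^3 - 2 * u^2 + u) * h * ma +
        (-2 * u^3 + 3 * u^2) * yb + (u^3 - u^2) * h * mb
    } else {
      ((6 * u^2 - 6 * u) * ya + (3 * u^2 - 4 * u + 1) * h * ma +
         (-6 * u^2 + 6 * u) * yb + (3 * u^2 - 2 * u) * h * mb) / h
    }
  }
  function(t, deriv = 0) {
    out <- numeric(length(t))
    lo <- t <= x[1]; hi <- t >= x[3]
    s1 <- t > x[1] & t <= x[2]; s2 <- t > x[2] & t < x[3]
    out[lo] <- if (deriv == 0) y[1] else 0
    out[hi] <- if (deriv == 0) y[3] else 0
    if (any(s1)) out[s1] <- hermite(t[s1], x[1], x[2], y[1], y[2], 0, m2, deriv)
    if (any(s2)) out[s2] <- hermite(t[s2], x[2], x[3], y[2], y[3], m2, 0, deriv)
    out
  }
}

#' Detect candidate boundary windows in an intensity profile
#'
#' Smooths the profile with a short moving average, reduces it to its
#' alternating local extrema, prunes extrema pairs whose amplitude falls
#' below `min_amplitude` (persistence-style simplification), and reports
#' one window per surviving monotone rise or fall. Window edges are trimmed
#' to where the profile departs from the flanking plateau levels by 5% of
#' the segment amplitude, so the window spans the 5%--95% transition.
#'
#' @param profile An `expression_profile` with an `intensity` column.
#' @param min_amplitude Minimum rise/fall amplitude in intensity units
#'   (default 30).
#' @param smooth_window Moving-average width in samples (default 5);
#'   detection only -- fitting uses the raw profile.
#' @param pole_margin_pct Windows touching the first/last this-many %EL are
#'   discarded (default 2): at the embryo poles the strip leaves the mask
#'   and the profile steps to the slide background, which is not an
#'   expression boundary. Applied only when the profile carries `pct_el`.
#' @return List of windows, each `list(x_lo, x_hi, direction)` with
#'   `direction` `"rising"` or `"falling"`; empty for flat profiles.
#' @export
detect_boundary_windows <- function(profile, min_amplitude = 30,
                                    smooth_window = 5,
                                    pole_margin_pct = 2) {
  stopifnot("intensity" %in% names(profile))
  if (!is.null(profile$pct_el)) {
    # drop the pole regions before looking for extrema: the step where the
    # strip leaves the mask otherwise merges with a genuine boundary ramp
    profile <- profile[profile$pct_el >= pole_margin_pct &
                         profile$pct_el <= 100 - pole_margin_pct, ,
                       drop = FALSE]
  }
  s <- moving_average(profile$intensity, smooth_window)
  n <- length(s)
  if (n < 5) return(list())
  ext <- find_extrema(s)
  ext <- prune_extrema(s, ext, min_amplitude)
  if (length(ext) < 2) return(list())
  wins <- list()
  for (i in seq_len(length(ext) - 1)) {
    i0 <- ext[i]; i1 <- ext[i + 1]
    amp <- s[i1] - s[i0]
    if (abs(amp) < min_amplitude) next
    tol <- 0.05 * abs(amp)
    seg <- s[i0:i1]
    ihalf <- which.min(abs(seg - (seg[1] + amp / 2)))
    near_lo <- which(abs(seg - seg[1]) <= tol & seq_along(seg) <= ihalf)
    near_hi <- which(abs(seg - seg[length(seg)]) <= tol &
                       seq_along(seg) >= ihalf)
    j_lo <- i0 + (if (length(near_lo)) max(near_lo) else 1L) - 1L
    j_hi <- i0 + (if (length(near_hi)) min(near_hi) else length(seg)) - 1L
    wins[[length(wins) + 1]] <- list(
      x_lo = profile$x[j_lo], x_hi = profile$x[j_hi],
      direction = if (amp > 0) "rising" else "falling")
  }
  if (!is.null(profile$pct_el) && length(wins)) {
    pel <- stats::approxfun(profile$x, profile$pct_el, rule = 2)
    keep <- vapply(wins, function(w)
      pel(w$x_lo) >= pole_margin_pct && pel(w$x_hi) <= 100 - pole_margin_pct,
      logical(1))
    wins <- wins[keep]
  }
  wins
}

# Indices of alternating local extrema of s, including both endpoints.
find_extrema <- function(s) {
  d <- diff(s)
  sgn <- sign(d)
  nz <- which(sgn != 0)
  if (length(nz) == 0) return(c(1L, length(s)))
  ext <- 1L
  cur <- sgn[nz[1]]
  for (k in nz[-1]) {
    if (sgn[k] != cur) {
      ext <- c(ext, k)  # turning point at start of the new run
      cur <- sgn[k]
    }
  }
  unique(c(ext, length(s)))
}

# Persistence-style pruning: repeatedly drop the extrema bounding the
# smallest-amplitude segment until all segments clear min_amplitude.
prune_extrema <- function(s, ext, min_amplitude) {
  repeat {
    if (length(ext) < 2) return(ext)
    amps <- abs(diff(s[ext]))
    k <- which.min(amps)
    if (amps[k] >= min_amplitude) return(ext)
    if (length(ext) == 2) return(ext[0])
    if (k == 1) ext <- ext[-2]
    else if (k == length(ext) - 1) ext <- ext[-(length(ext) - 1)]
    else ext <- ext[-c(k, k + 1)]
    # restore alternation: drop interior points not separating direction
    keep <- rep(TRUE, length(ext))
    if (length(ext) > 2) {
      v <- s[ext]
      for (i in 2:(length(ext) - 1))
        if ((v[i] - v[i - 1]) * (v[i + 1] - v[i]) >= 0) keep[i] <- FALSE
      ext <- ext[keep]
    }
  }
}

#' Fit a clamped spline to one boundary window
#'
#' Control points are initialised from the window: `x1`, `x3` at the
#' window's plateau edges with `y1`, `y3` the median intensity over a small
#' shoulder outside each edge; `x2` at the half-amplitude crossing with
#' `y2 = (y1 + y3) / 2`. The abscissae `(x1, x2, x3)` are then refined by
#' least squares against the raw profile restricted to the window
#' (Nelder-Mead, at most `max_iter` iterations); non-convergence returns
#' the current fit flagged. `overrides` (a 3x2 matrix / data frame of
#' control points) bypasses initialisation and refinement entirely,
#' mirroring manual curation.
#'
#' @param profile Profile with `intensity` (and ideally `pct_el`).
#' @param window One window from [detect_boundary_windows()].
#' @param overrides Optional 3 `(x, y)` control points used verbatim.
#' @param max_iter Refinement iteration cap (default 100).
#' @return A `boundary_fit`: list with `control_points` (3-row data frame
#'   `x`, `y` in intensity space), `fun` (the clamped spline),
#'   `direction`, `converged`, `window`.
#' @export
fit_clamped_boundary <- function(profile, window, overrides = NULL,
                                 max_iter = 100) {
  if (!is.null(overrides)) {
    ov <- as.data.frame(overrides); names(ov) <- c("x", "y")
    stopifnot(nrow(ov) == 3L)
    return(new_boundary_fit(ov, direction = if (ov$y[3] >= ov$y[1])
      "rising" else "falling", converged = TRUE, window = window))
  }
  idx <- which(profile$x >= window$x_lo & profile$x <= window$x_hi)
  if (length(idx) < 4) stop("boundary window too narrow to fit")
  xs <- profile$x[idx]; ys <- profile$intensity[idx]
  sm <- moving_average(ys, 5)
  amp <- sm[length(sm)] - sm[1]
  counter <- if (amp >= 0) max(cummax(sm) - sm) else max(sm - cummin(sm))
  if (abs(amp) < 1e-9 || counter > 0.5 * abs(amp))
    stop("ambiguous boundary: window is not monotone")

  shoulder <- function(side) {
    # robust plateau level from samples just outside the window edge
    k <- max(3L, round(0.1 * length(idx)))
    if (side == "lo") {
      sel <- which(profile$x >= window$x_lo - k & profile$x <= window$x_lo)
    } else {
      sel <- which(profile$x >= window$x_hi & profile$x <= window$x_hi + k)
    }
    if (length(sel) == 0) sel <- if (side == "lo") idx[1] else idx[length(idx)]
    stats::median(profile$intensity[sel])
  }
  y1 <- shoulder("lo"); y3 <- shoulder("hi")
  y2 <- (y1 + y3) / 2
  x2 <- xs[which.min(abs(ys - y2))]
  x1 <- window$x_lo; x3 <- window$x_hi
  if (x2 <= x1) x2 <- x1 + 0.25 * (x3 - x1)
  if (x2 >= x3) x2 <- x3 - 0.25 * (x3 - x1)

  obj <- function(p) {
    if (!(p[1] < p[2] && p[2] < p[3])) return(1e18)
    f <- clamped_spline(p, c(y1, y2, y3))
    sum((f(xs) - ys)^2)
  }
  opt <- stats::optim(c(x1, x2, x3), obj, method = "Nelder-Mead",
                      control = list(maxit = max_iter))
  converged <- opt$convergence == 0 && is.finite(opt$value) && opt$value < 1e17
  p <- if (converged) opt$par else c(x1, x2, x3)
  new_boundary_fit(data.frame(x = p, y = c(y1, y2, y3)),
                   direction = if (y3 >= y1) "rising" else "falling",
                   converged = converged, window = window)
}

new_boundary_fit <- function(control_points, direction, converged, window,
                             boundary_id = NA_integer_, facing = NA_character_,
                             gene = NA_character_, channel = NA_character_) {
  stopifnot(control_points$x[1] < control_points$x[2],
            control_points$x[2] < control_points$x[3])
  structure(list(control_points = control_points,
                 fun = clamped_spline(control_points$x, control_points$y),
                 direction = direction, converged = converged,
                 window = window, boundary_id = boundary_id, facing = facing,
                 gene = gene, channel = channel),
            class = "boundary_fit")
}

#' Boundary position and width in % embryo length
#'
#' Position is the %EL of the mid control point (half-amplitude point);
#' width is the %EL span between the outer control points.
#'
#' @param fit A `boundary_fit`.
#' @param mask The aligned [embryo_mask] defining the %EL axis.
#' @return Named numeric `c(position_pct_el, width_pct_el)`.
#' @export
position_and_width <- function(fit, mask) {
  stopifnot(inherits(fit, "boundary_fit"), inherits(mask, "embryo_mask"))
  x_min <- mask$bbox[["c1"]]; x_max <- mask$bbox[["c2"]]
  pel <- function(x) 100 * (x - x_min) / (x_max - x_min)
  cp <- fit$control_points
  c(position_pct_el = pel(cp$x[2]),
    width_pct_el = pel(cp$x[3]) - pel(cp$x[1]))
}

#' The gene-specific boundary-ID catalogue
#'
#' Maps each gene to its ordered list of (boundary_id, facing) along the
#' A--P axis. IDs are kept consistent with homologous boundaries across
#' species, which leaves gaps: e.g. *gt* uses IDs 2, 5, 6, 7 with 3--4
#' reserved. The default table ships with the package and is editable
#' configuration.
#'
#' @param path Optional path to a replacement catalogue CSV with columns
#'   `gene`, `boundary_id`, `facing`.
#' @return Data frame `gene`, `boundary_id`, `facing`, ordered A--P within
#'   gene.
#' @export
boundary_catalogue <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "boundary_catalogue.csv",
                        package = "blastoquant")
  cat <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "boundary_id", "facing") %in% names(cat)))
  if (any(duplicated(cat[c("gene", "boundary_id")])))
    stop("boundary catalogue has duplicated IDs within a gene")
  cat
}

#' Assign catalogue boundary IDs to fitted boundaries
#'
#' Fits are ranked by A--P position (mid control point) and matched 1:1,
#' in rank order, against the gene's catalogue entries. When the counts
#' disagree, the first `min(n)` ranks are assigned and the remainder are
#' flagged (`assigned = FALSE`), never dropped.
#'
#' @param fits List of `boundary_fit`s for one embryo and gene.
#' @param gene Gene abbreviation present in the catalogue.
#' @param catalogue Catalogue data frame from [boundary_catalogue()].
#' @return The fits, each with `boundary_id`, `facing`, `gene` and an
#'   `assigned` flag filled in, sorted by position.
#' @export
assign_boundary_ids <- function(fits, gene, catalogue = boundary_catalogue()) {
  entries <- catalogue[catalogue$gene == gene, , drop = FALSE]
  if (nrow(entries) == 0)
    stop("unknown gene '", gene, "'; catalogue knows: ",
         paste(sort(unique(catalogue$gene)), collapse = ", "))
  if (length(fits) == 0) return(fits)
  pos <- vapply(fits, function(f) f$control_points$x[2], numeric(1))
  fits <- fits[order(pos)]
  n_assign <- min(length(fits), nrow(entries))
  for (i in seq_along(fits)) {
    if (i <= n_assign) {
      fits[[i]]$boundary_id <- as.integer(entries$boundary_id[i])
      fits[[i]]$facing <- entries$facing[i]
      fits[[i]]$assigned <- TRUE
    } else {
      fits[[i]]$boundary_id <- NA_integer_
      fits[[i]]$facing <- NA_character_
      fits[[i]]$assigned <- FALSE
    }
    fits[[i]]$gene <- gene
  }
  if (length(fits) != nrow(entries))
    warning("gene ", gene, ": ", length(fits), " fitted boundaries vs ",
            nrow(entries), " catalogue entries; extras flagged unassigned")
  fits
}

# Convert boundary fits to table rows in the on-disk graph convention
# (y origin at the upper-left of the profile graph: stored y = 255 -
# intensity, increasing downward).
boundary_fits_to_rows <- function(fits, embryo_path, channel) {
  rows <- lapply(fits, function(f) {
    cp <- f$control_points
    data.frame(embryo = embryo_path,
               boundary_id = f$boundary_id,
               facing = f$facing,
               gene = f$gene,
               channel = channel,
               boundary_x1 = cp$x[1], boundary_x2 = cp$x[2],
               boundary_x3 = cp$x[3],
               boundary_y1 = 255 - cp$y[1], boundary_y2 = 255 - cp$y[2],
               boundary_y3 = 255 - cp$y[3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
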