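# Synthetic embryo-image generator.
#
# Produces the four-image quadruplet the quantification pipeline consumes
# (bright-field stain, DIC morphology, nuclear counterstain, membrane
# detail), with a ground-truth manifest recording the generating geometry,
# expression boundaries and stage. The forward stain model is chosen so the
# pipeline's channel-unmixing formulas are its exact inverse up to noise:
# pixel colour is a linear mix of an unstained background colour and a
# full-stain colour, weighted by the local stain strength, which ramps
# through each expression boundary as a logistic in % embryo length.

#' Embryo geometry for the synthetic generator
#'
#' @param semi_major_px,semi_minor_px Ellipse semi-axes in pixels
#'   (`semi_major_px > semi_minor_px > 0`).
#' @param center_xy `(x, y)` pixel coordinates of the ellipse centre
#'   (origin upper-left, x rightward, y downward).
#' @param rotation_deg Counter-clockwise angle (as seen on screen) of the
#'   major axis from horizontal, in `(-90, 90]`.
#' @param anterior_on_left Whether the anterior pole sits on the left end of
#'   the major axis once the embryo is de-rotated.
#' @return An `embryo_geometry` object.
#' @export
embryo_geometry <- function(semi_major_px = 300, semi_minor_px = 120,
                            center_xy = c(350, 175), rotation_deg = 0,
                            anterior_on_left = TRUE) {
  stopifnot(semi_major_px > semi_minor_px, semi_minor_px > 0,
            length(center_xy) == 2L,
            rotation_deg > -90, rotation_deg <= 90,
            is.logical(anterior_on_left))
  structure(list(semi_major_px = semi_major_px, semi_minor_px = semi_minor_px,
                 center_xy = as.numeric(center_xy),
                 rotation_deg = rotation_deg,
                 anterior_on_left = anterior_on_left),
            class = "embryo_geometry")
}

#' Expression-domain specification
#'
#' Describes the stained pattern of one gene as an ordered list of
#' expression boundaries along the A--P axis. Each boundary faces either
#' `anterior` (anterior edge of its domain: stain rises moving posteriorly)
#' or `posterior` (posterior edge: stain falls). Facings must alternate and
#' positions must be strictly increasing.
#'
#' @param gene Gene abbreviation (e.g. `"gt"`).
#' @param boundaries Data frame with columns `boundary_id` (integer),
#'   `facing` (`"anterior"`/`"posterior"`), `position_pct_el` (in
#'   `[0, 100]` %EL), `width_pct_el` (> 0), `plateau_intensity` (in `[0, 1]`).
#' @param stain `"NBT_BCIP"` or `"FASTRED"`.
#' @return A `domain_spec` object.
#' @export
domain_spec <- function(gene, boundaries, stain = c("NBT_BCIP", "FASTRED")) {
  stain <- match.arg(stain)
  b <- as.data.frame(boundaries)
  need <- c("boundary_id", "facing", "position_pct_el", "width_pct_el",
            "plateau_intensity")
  if (!all(need %in% names(b))) stop("boundaries must have columns: ",
                                     paste(need, collapse = ", "))
  if (nrow(b) > 0) {
    stopifnot(all(b$facing %in% c("anterior", "posterior")),
              all(b$position_pct_el >= 0 & b$position_pct_el <= 100),
              all(b$width_pct_el > 0),
              all(b$plateau_intensity >= 0 & b$plateau_intensity <= 1))
    if (is.unsorted(b$position_pct_el, strictly = TRUE))
      stop("boundary positions must be strictly increasing along A-P")
    if (nrow(b) > 1 && any(b$facing[-1] == b$facing[-nrow(b)]))
      stop("boundary facings must alternate anterior/posterior")
    gap <- diff(b$position_pct_el)
    need_gap <- (b$width_pct_el[-nrow(b)] + b$width_pct_el[-1]) / 2
    if (nrow(b) > 1 && any(gap < need_gap))
      stop("boundary ramps overlap: consecutive boundaries closer than ",
           "the mean of their widths")
  }
  structure(list(gene = gene, boundaries = b, stain = stain),
            class = "domain_spec")
}

#' Stain colour model
#'
#' Linear colour mixing between an unstained embryo background and a fully
#' stained colour; the mixing weight is the local stain strength. Defaults
#' encode the two colorimetric reagents: NBT/BCIP (purple) strongly absorbs
#' the red channel, FastRed depresses green relative to red.
#'
#' @param stain `"NBT_BCIP"` or `"FASTRED"`.
#' @param background_rgb,full_stain_rgb Length-3 RGB vectors in `[0, 255]`.
#' @return A `stain_color_model` object.
#' @export
stain_color_model <- function(stain = c("NBT_BCIP", "FASTRED"),
                              background_rgb = NULL, full_stain_rgb = NULL) {
  stain <- match.arg(stain)
  if (is.null(background_rgb))
    background_rgb <- c(225, 215, 190) # pale yellow-ish unstained tissue
  if (is.null(full_stain_rgb))
    full_stain_rgb <- switch(stain,
      NBT_BCIP = c(55, 45, 95),   # purple: red far below background red
      FASTRED  = c(215, 55, 80))  # red: green far below red
  stopifnot(length(background_rgb) == 3L, length(full_stain_rgb) == 3L,
            all(background_rgb >= 0 & background_rgb <= 255),
            all(full_stain_rgb >= 0 & full_stain_rgb <= 255))
  if (stain == "NBT_BCIP" && full_stain_rgb[1] >= background_rgb[1] - 50)
    stop("NBT_BCIP full-stain red must be well below background red")
  if (stain == "FASTRED" && full_stain_rgb[2] >= full_stain_rgb[1] - 50)
    stop("FASTRED full-stain green must be well below its red")
  structure(list(stain = stain, background_rgb = background_rgb,
                 full_stain_rgb = full_stain_rgb),
            class = "stain_color_model")
}

#' Canvas size accommodating a rotated embryo
#'
#' Smallest `(height, width)` canvas (plus margin) that contains the
#' rotated ellipse, with the centre placed mid-canvas. Use this to build a
#' matching `center_xy`/`canvas` pair for rotated geometries.
#'
#' @param semi_major_px,semi_minor_px,rotation_deg As in
#'   [embryo_geometry()].
#' @param margin_px Clearance around the ellipse (default 25).
#' @return List with `canvas` `(height, width)` and `center_xy` `(x, y)`.
#' @export
canvas_for_geometry <- function(semi_major_px, semi_minor_px, rotation_deg,
                                margin_px = 25) {
  th <- abs(rotation_deg * pi / 180)
  half_w <- semi_major_px * cos(th) + semi_minor_px * sin(th)
  half_h <- semi_major_px * sin(th) + semi_minor_px * cos(th)
  w <- 2 * ceiling(half_w + margin_px)
  h <- 2 * ceiling(half_h + margin_px)
  list(canvas = c(h, w), center_xy = c(w / 2, h / 2))
}

# Logistic ramp steepness such that the 5%-95% rise spans `width` %EL.
ramp_scale <- function(width) width / (2 * log(19))

# Stain strength s(pct) in [0,1] along the A-P axis for a domain_spec.
stain_strength <- function(domains, pct) {
  b <- domains$boundaries
  s <- rep(0, length(pct))
  if (nrow(b) == 0) return(s)
  if (b$facing[1] == "posterior") s <- s + b$plateau_intensity[1]
  for (i in seq_len(nrow(b))) {
    L <- stats::plogis(pct, location = b$position_pct_el[i],
                       scale = ramp_scale(b$width_pct_el[i]))
    sgn <- if (b$facing[i] == "anterior") 1 else -1
    s <- s + sgn * b$plateau_intensity[i] * L
  }
  pmin(pmax(s, 0), 1)
}

# Elliptical (u, v) coordinates of every canvas pixel for a geometry:
# u along the major axis, v along the minor axis.
ellipse_coords <- function(geom, h, w) {
  th <- geom$rotation_deg * pi / 180
  x <- rep(seq_len(w), each = h) - geom$center_xy[1]
  y <- rep(seq_len(h), times = w) - geom$center_xy[2]
  # inverse of the screen-CCW forward map (see rotate_raster)
  list(u = matrix(x * cos(th) - y * sin(th), h, w),
       v = matrix(x * sin(th) + y * cos(th), h, w))
}

# A-P position in %EL for elliptical coordinate u.
axial_pct <- function(u, geom) {
  a <- geom$semi_major_px
  if (geom$anterior_on_left) (u + a) / (2 * a) * 100 else (a - u) / (2 * a) * 100
}

add_noise <- function(img, sd) {
  if (sd <= 0) return(round(clip255(img)))
  round(clip255(img + stats::rnorm(length(img), sd = sd)))
}

# Deterministic quasi-uniform nucleus placement: a jittered square grid in
# the ellipse frame, spacing chosen so at least n cells fall inside a
# slightly shrunken ellipse. Guarantees a minimum centre separation of
# spacing/2, so peaks stay resolvable even at cycle 14 (8192 nuclei).
place_nuclei <- function(geom, n) {
  a <- geom$semi_major_px * 0.96
  b <- geom$semi_minor_px * 0.96
  s <- sqrt(pi * a * b / n)
  repeat {
    gx <- seq(-a, a, by = s)
    gy <- seq(-b, b, by = s)
    gu <- rep(gx, times = length(gy))
    gv <- rep(gy, each = length(gx))
    inside <- (gu / a)^2 + (gv / b)^2 <= 1
    if (sum(inside) >= n) break
    s <- s * 0.97
  }
  idx <- sample(which(inside), n)
  jit <- s / 4
  u <- gu[idx] + stats::runif(n, -jit, jit)
  v <- gv[idx] + stats::runif(n, -jit, jit)
  th <- geom$rotation_deg * pi / 180
  list(x = geom$center_xy[1] + u * cos(th) + v * sin(th),
       y = geom$center_xy[2] - u * sin(th) + v * cos(th),
       spacing = s)
}

# Stamp Gaussian intensity peaks (amplitude 255) at the given centres.
render_nuclei <- function(h, w, x, y, sigma) {
  img <- matrix(0, h, w)
  r <- max(1L, ceiling(3 * sigma))
  off <- -r:r
  for (i in seq_along(x)) {
    cx <- x[i]; cy <- y[i]
    cols <- round(cx) + off; rows <- round(cy) + off
    ok_c <- cols >= 1 & cols <= w; ok_r <- rows >= 1 & rows <= h
    if (!any(ok_c) || !any(ok_r)) next
    dx <- cols[ok_c] - cx; dy <- rows[ok_r] - cy
    patch <- 255 * exp(-(outer(dy^2, dx^2, "+")) / (2 * sigma^2))
    sub <- img[rows[ok_r], cols[ok_c], drop = FALSE]
    img[rows[ok_r], cols[ok_c]] <- pmax(sub, patch)
  }
  img
}

#' Generate one synthetic embryo quadruplet with ground truth
#'
#' Renders the four registered images of one stained blastoderm embryo:
#' bright-field (stain rendered as logistic ramps between the background and
#' full-stain colours), DIC-like morphology (dark textured interior with a
#' strong edge, for masking), nuclear counterstain (exactly `2^(cycle-1)`
#' intensity peaks inside the ellipse), and membrane detail (a dark front
#' whose depth fraction encodes the C14A time class). Deterministic for a
#' given seed.
#'
#' @param geometry An [embryo_geometry()].
#' @param domains A [domain_spec()] (or list of them; single-stain rendering
#'   uses the first).
#' @param stage Stage label (`"C1"`..`"C13"`, `"C14_T1"`..`"C14_T8"`) or a
#'   [time_class] object.
#' @param noise_sd Gaussian pixel noise sd in intensity units (0--255 scale).
#' @param seed Integer random seed.
#' @param canvas `(height, width)` of all four rasters, pixels.
#' @param colors Optional [stain_color_model()]; default derived from the
#'   domain spec's stain.
#' @return List with `record` (an [embryo_record]) and `truth` (ground-truth
#'   manifest entry: geometry, stage, nucleus count, boundary table, seed).
#' @export
generate_embryo <- function(geometry, domains, stage = "C14_T4",
                            noise_sd = 0, seed = 1L,
                            canvas = c(350, 700), colors = NULL) {
  stopifnot(inherits(geometry, "embryo_geometry"))
  if (inherits(domains, "domain_spec")) domains <- list(domains)
  stopifnot(length(domains) >= 1L, inherits(domains[[1]], "domain_spec"))
  dom <- domains[[1]]
  if (inherits(stage, "time_class")) tc <- stage else tc <- time_class(stage)
  h <- canvas[1]; w <- canvas[2]
  g <- geometry
  th <- abs(g$rotation_deg * pi / 180)
  half_w <- g$semi_major_px * cos(th) + g$semi_minor_px * sin(th)
  half_h <- g$semi_major_px * sin(th) + g$semi_minor_px * cos(th)
  if (g$center_xy[1] - half_w < 1 || g$center_xy[1] + half_w > w ||
      g$center_xy[2] - half_h < 1 || g$center_xy[2] + half_h > h)
    stop("embryo does not fit inside the requested canvas")
  if (is.null(colors)) colors <- stain_color_model(dom$stain)

  set.seed(as.integer(seed))
  ec <- ellipse_coords(g, h, w)
  r2 <- (ec$u / g$semi_major_px)^2 + (ec$v / g$semi_minor_px)^2
  inside <- r2 <= 1

  # bright-field: linear colour mixing weighted by local stain strength
  pct <- axial_pct(ec$u, g)
  s <- matrix(0, h, w)
  s[inside] <- stain_strength(dom, pct[inside])
  bf <- array(0, c(h, w, 3))
  for (k in 1:3) {
    plane <- matrix(245 - (k - 1) * 3, h, w)  # neutral bright surround
    plane[inside] <- colors$background_rgb[k] +
      s[inside] * (colors$full_stain_rgb[k] - colors$background_rgb[k])
    bf[, , k] <- plane
  }
  bf <- add_noise(bf, noise_sd)

  # DIC: bright surround, darker textured interior, strong dark edge band
  dic <- matrix(225, h, w)
  dic[inside] <- 120 + stats::runif(sum(inside), -20, 20)
  edge <- r2 <= 1 & r2 >= 0.90
  dic[edge] <- 55
  dic <- add_noise(dic, noise_sd)

  # nuclear counterstain: exactly 2^(cycle-1) peaks inside the ellipse
  n_nuc <- nuclei_for_cycle(tc$cycle)
  np <- place_nuclei(g, n_nuc)
  nuc <- render_nuclei(h, w, np$x, np$y,
                       sigma = min(2.5, max(0.7, np$spacing / 5)))
  nuc <- add_noise(nuc, noise_sd)

  # membrane detail: dark cellularisation front at fraction depth of frame
  depth <- if (tc$cycle == 14L) (tc$subclass - 0.5) / 8 else 0
  memb <- matrix(220, h, w)
  nfront <- round(depth * h)
  if (nfront > 0) memb[seq_len(nfront), ] <- 40
  memb <- add_noise(memb, noise_sd)

  record <- embryo_record(
    embryo_id = "001", batch_id = paste0("ma_", dom$gene, "_synthetic"),
    images = list(
      `_ch00`      = bf,
      `_dic_ch00`  = array(rep(dic, 3), c(h, w, 3)),
      `_nuc_ch00`  = array(rep(nuc, 3), c(h, w, 3)),
      `_memb_ch00` = array(rep(memb, 3), c(h, w, 3))),
    gene = dom$gene, channel = stain_channel(dom$stain))

  truth <- list(geometry = g, domains = dom, stage = tc$label,
                cycle = tc$cycle, n_nuclei = n_nuc,
                membrane_depth = depth, noise_sd = noise_sd,
                seed = as.integer(seed))
  list(record = record, truth = truth)
}

# Stain token -> channel colour name used in the boundary tables.
stain_channel <- function(stain) switch(stain, NBT_BCIP = "purple",
                                        FASTRED = "red",
                                        stop("unknown stain ", stain))

#' Generate a batch of synthetic embryos on disk
#'
#' Writes the standard batch directory hierarchy (see [layout_paths()]) with
#' the four per-embryo PNGs, plus a `manifest.csv` ground-truth table in the
#' batch directory. Geometry is jittered per embryo (semi-axes +-8%,
#' rotation uniform in +-25 degrees) around the defaults.
#'
#' @param spec List describing the batch: `n_embryos` (>= 1), `gene`,
#'   `stain`, `boundaries` (data frame as in [domain_spec()]), `stage`
#'   (single label or vector recycled over embryos), `noise_sd`, `date`
#'   (DDMMYY token, default `"010116"`), `species` (default `"ma"`).
#' @param out_dir Root output directory (the `ish/` tree is created below it).
#' @param seed Integer seed; per-embryo seeds are derived from it.
#' @param overwrite Refuse to write into an existing non-empty batch
#'   directory unless `TRUE`.
#' @return The ground-truth manifest as a data frame (invisibly also written
#'   to `manifest.csv`).
#' @export
generate_batch <- function(spec, out_dir, seed = 1L, overwrite = FALSE) {
  if (is.null(spec$n_embryos) || spec$n_embryos < 1)
    stop("batch spec must list at least one embryo")
  n <- as.integer(spec$n_embryos)
  gene <- spec$gene %||% "gt"
  stain <- spec$stain %||% "NBT_BCIP"
  species <- spec$species %||% "ma"
  date <- spec$date %||% "010116"
  noise_sd <- spec$noise_sd %||% 0
  stages <- rep(spec$stage %||% "C14_T4", length.out = n)
  boundaries <- spec$boundaries %||% default_boundaries(gene)

  batch <- batch_id(species, gene, date)
  batch_dir <- file.path(out_dir, dirname(layout_paths(batch, "001", "_ch00")))
  if (dir.exists(batch_dir) && length(list.files(batch_dir)) > 0 && !overwrite)
    stop("output batch directory ", batch_dir,
         " is not empty; set overwrite = TRUE to replace it")
  dir.create(batch_dir, recursive = TRUE, showWarnings = FALSE)

  set.seed(as.integer(seed))
  embryo_seeds <- sample.int(2^30, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(embryo_seeds[i])
    a <- 300 * stats::runif(1, 0.92, 1.08)
    b <- 120 * stats::runif(1, 0.92, 1.08)
    rot <- stats::runif(1, -25, 25)
    cv <- canvas_for_geometry(a, b, rot)
    geom <- embryo_geometry(a, b, cv$center_xy, rot, TRUE)
    dom <- domain_spec(gene, boundaries, stain)
    ge <- generate_embryo(geom, dom, stages[i], noise_sd, embryo_seeds[i],
                          canvas = cv$canvas)
    id <- sprintf("%03d", i)
    ge$record$embryo_id <- id
    ge$record$batch_id <- format(batch)
    for (sfx in names(ge$record$images))
      write_raster_png(ge$record$images[[sfx]],
                       file.path(out_dir, layout_paths(batch, id, sfx)))
    rows[[i]] <- data.frame(
      embryo_id = id, batch_id = format(batch),
      semi_major_px = a, semi_minor_px = b,
      center_x = cv$center_xy[1], center_y = cv$center_xy[2],
      rotation_deg = rot,
      anterior_on_left = TRUE, stage = stages[i],
      cycle = ge$truth$cycle, n_nuclei = ge$truth$n_nuclei,
      gene = gene, stain = stain, noise_sd = noise_sd,
      seed = embryo_seeds[i],
      boundaries = pack_boundaries(boundaries),
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(batch_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest
}

# Compact lossless text encoding of a boundary table for the manifest:
# "id:facing:position:width:intensity" records joined with ";".
pack_boundaries <- function(b) {
  paste(sprintf("%d:%s:%.6g:%.6g:%.6g", b$boundary_id, b$facing,
                b$position_pct_el, b$width_pct_el, b$plateau_intensity),
        collapse = ";")
}

#' @rdname generate_batch
#' @param packed A packed boundary string from a manifest.
#' @export
unpack_boundaries <- function(packed) {
  parts <- strsplit(strsplit(packed, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(
    boundary_id = vapply(parts, function(p) as.integer(p[1]), integer(1)),
    facing = vapply(parts, `[`, character(1), 2),
    position_pct_el = vapply(parts, function(p) as.numeric(p[3]), numeric(1)),
    width_pct_el = vapply(parts, function(p) as.numeric(p[4]), numeric(1)),
    plateau_intensity = vapply(parts, function(p) as.numeric(p[5]), numeric(1)),
    stringsAsFactors = FALSE)
}

# Default single-domain pattern used when a batch spec gives no boundaries.
default_boundaries <- function(gene) {
  data.frame(boundary_id = c(1L, 2L), facing = c("anterior", "posterior"),
             position_pct_el = c(35, 60), width_pct_el = c(6, 6),
             plateau_intensity = c(1, 1), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
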