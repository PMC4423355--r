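# Shared fixtures, all built in code.

# Analytic ellipse raster: rows/cols inside the (axis-aligned) ellipse.
# Used both as the ground-truth mask oracle and to fabricate masks of an
# exact pixel height (pick cy halfway between integer rows).
ellipse_raster <- function(h, w, cx, cy, a, b) {
  x <- rep(seq_len(w), each = h) - cx
  y <- rep(seq_len(h), times = w) - cy
  matrix(((x / a)^2 + (y / b)^2 <= 1) * 1L, h, w)
}

# Mask with an exact pixel height: semi-minor b = height/2, centre between
# rows, so rows cy-b..cy+b contain exactly `height` integer rows.
exact_height_mask <- function(height, aspect = 2.5) {
  b <- height / 2
  a <- aspect * b
  h <- ceiling(height) + 12L
  w <- ceiling(2 * a) + 12L
  cy <- (h + 1) / 2
  if (height %% 2 == 0) cy <- floor(cy) + 0.5 else cy <- floor(cy)
  m <- ellipse_raster(h, w, (w + 1) / 2, cy, a, b)
  blastoquant:::as_embryo_mask(m)
}

# The gt-like four-boundary test pattern (anterior + posterior domains
# abutting both poles).
gt_like_boundaries <- function(positions = c(25, 45, 62, 80),
                               widths = rep(6, 4)) {
  data.frame(boundary_id = c(2L, 5L, 6L, 7L),
             facing = c("posterior", "anterior", "posterior", "anterior"),
             position_pct_el = positions, width_pct_el = widths,
             plateau_intensity = 1, stringsAsFactors = FALSE)
}

# One interior expression domain (no stain at the poles).
single_domain_boundaries <- function(p1 = 35, p2 = 60, width = 6) {
  data.frame(boundary_id = 1:2, facing = c("anterior", "posterior"),
             position_pct_el = c(p1, p2), width_pct_el = width,
             plateau_intensity = 1, stringsAsFactors = FALSE)
}

# Compact synthetic embryo (smaller than the generator defaults) for tests
# where full resolution is not the point.
small_embryo <- function(boundaries = single_domain_boundaries(),
                         rotation_deg = 0, stage = "C10", noise_sd = 0,
                         seed = 1, gene = "gt", stain = "NBT_BCIP") {
  cv <- canvas_for_geometry(150, 60, rotation_deg)
  geom <- embryo_geometry(150, 60, cv$center_xy, rotation_deg)
  dom <- domain_spec(gene, boundaries, stain)
  generate_embryo(geom, dom, stage = stage, noise_sd = noise_sd,
                  seed = seed, canvas = cv$canvas)
}

# Full-size synthetic embryo at the generator's default scale.
full_embryo <- function(boundaries = gt_like_boundaries(),
                        rotation_deg = 0, stage = "C14_T4", noise_sd = 0,
                        seed = 1, gene = "gt", stain = "NBT_BCIP") {
  cv <- canvas_for_geometry(300, 120, rotation_deg)
  geom <- embryo_geometry(300, 120, cv$center_xy, rotation_deg)
  dom <- domain_spec(gene, boundaries, stain)
  generate_embryo(geom, dom, stage = stage, noise_sd = noise_sd,
                  seed = seed, canvas = cv$canvas)
}

# Mask -> aligned record -> %EL-mapped unmixed profile, via the standard
# chain; returns list(profile, mask, strip, fits) with detection run.
quantify_to_fits <- function(ge, min_amplitude = 30) {
  rec <- ge$record
  m <- compute_mask(rec$images[["_dic_ch00"]])
  al <- align_record(rec, m)
  path <- skeleton_midline(al$mask)
  sp <- place_knots(path, al$mask)
  strip <- make_strip(sp, al$mask)
  prof <- extract_rgb_profile(al$record$images[["_ch00"]], strip)
  prof <- unmix_nbt_bcip(prof)
  prof <- to_percent_el(prof, al$mask)
  wins <- detect_boundary_windows(prof, min_amplitude)
  fits <- lapply(wins, function(w) fit_clamped_boundary(prof, w))
  list(profile = prof, mask = al$mask, strip = strip, fits = fits,
       record = al$record)
}

# Straight horizontal strip covering columns x1..x2 at row y, for profile
# tests on fabricated images.
straight_strip <- function(x1, x2, y, height_px) {
  sp <- midline_spline(data.frame(x = seq(x1, x2, length.out = 5), y = y))
  structure(list(spline = sp, height_px = as.integer(height_px),
                 mask_height_px = 10 * height_px),
            class = "strip_band")
}
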