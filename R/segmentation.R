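# Segmentation: whole-embryo mask from the DIC image, then crop / rotate /
# mirror all registered images into the canonical anterior-left frame.

#' Construct an embryo record
#'
#' Bundles the four registered rasters of one embryo with its identifiers.
#' The bright-field (`_ch00`) and DIC (`_dic_ch00`) images are taken with
#' the same objective and must share dimensions; the membrane image
#' (`_memb_ch00`) is taken at higher magnification and is exempt from
#' registration.
#'
#' @param embryo_id Zero-padded 3-digit id string (e.g. `"001"`).
#' @param batch_id Batch id string `species_stain_date`.
#' @param images Named list of rasters; names from `_ch00`, `_dic_ch00`,
#'   `_nuc_ch00`, `_memb_ch00`.
#' @param gene Gene abbreviation(s).
#' @param channel Stain colour(s), `"purple"` or `"red"`.
#' @param is_rnai Whether the embryo comes from an RNAi-treated background.
#' @return An `embryo_record` object.
#' @export
embryo_record <- function(embryo_id, batch_id, images, gene, channel,
                          is_rnai = FALSE) {
  stopifnot(is.list(images), "_ch00" %in% names(images))
  if (all(c("_ch00", "_dic_ch00") %in% names(images))) {
    d1 <- dim(images[["_ch00"]]); d2 <- dim(images[["_dic_ch00"]])
    if (!all(d1[1:2] == d2[1:2]))
      stop("bright-field and DIC images must share dimensions")
  }
  structure(list(embryo_id = embryo_id, batch_id = batch_id, images = images,
                 gene = gene, channel = channel, is_rnai = is_rnai),
            class = "embryo_record")
}

#' Compute a whole-embryo mask from a DIC image
#'
#' Automatic (Otsu) intensity thresholding selects the dark embryo against
#' the bright DIC background; morphological closing bridges texture gaps,
#' the largest connected component is kept, and interior holes are filled.
#' The result must be a single ellipse-like component: its foreground
#' fraction within its bounding box has to fall in `[0.5, 0.95]`.
#'
#' @param dic DIC raster (matrix or RGB array, 0--255).
#' @param min_frame_frac Minimum fraction of the frame the embryo must
#'   cover (default 0.05); below this the image is declared empty.
#' @return An `embryo_mask` object: binary `mask` matrix, `bbox`
#'   `(r1, r2, c1, c2)`, `height_px` (vertical extent), `centroid` `(x, y)`,
#'   and `angle_deg` (principal-axis angle, screen-CCW from horizontal).
#' @export
compute_mask <- function(dic, min_frame_frac = 0.05) {
  g <- raster_grey(dic)
  thr <- 255 * EBImage::otsu(g / 255)
  fg <- (g < thr) * 1L
  fg <- EBImage::closing(fg, EBImage::makeBrush(7, shape = "disc"))
  lab <- EBImage::bwlabel(fg)
  n_comp <- max(lab)
  if (n_comp == 0) stop("no embryo found: empty threshold result")
  sizes <- tabulate(lab[lab > 0], nbins = n_comp)
  if (max(sizes) < min_frame_frac * length(g))
    stop("no embryo found: largest component covers <",
         round(100 * min_frame_frac), "% of the frame")
  if (n_comp > 1 && sort(sizes, decreasing = TRUE)[2] >= 0.5 * max(sizes))
    stop("multiple embryos: two comparable components in frame")
  keep <- which.max(sizes)
  m <- (lab == keep) * 1L
  m <- EBImage::fillHull(m)
  as_embryo_mask(m)
}

#' Build an embryo mask object from a binary matrix
#'
#' Derives the bounding box, pixel height/width, centroid and
#' principal-axis angle of a binary foreground matrix. Used internally by
#' [compute_mask()] and [align_record()]; exported so that masks can also
#' be constructed analytically (e.g. exact ellipse rasters in simulation
#' studies).
#'
#' @param m Binary matrix (1 = embryo).
#' @param check Enforce the ellipse-likeness sanity band (foreground fills
#'   0.5--0.95 of its bounding box).
#' @return An `embryo_mask` object.
#' @export
as_embryo_mask <- function(m, check = TRUE) {
  idx <- which(m > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("no embryo found: mask is empty")
  rs <- range(idx[, 1]); cs <- range(idx[, 2])
  bbox <- c(r1 = rs[1], r2 = rs[2], c1 = cs[1], c2 = cs[2])
  frac <- nrow(idx) / ((diff(rs) + 1) * (diff(cs) + 1))
  if (check && (frac < 0.5 || frac > 0.95))
    stop(sprintf(paste0("mask is not ellipse-like: foreground fills %.2f of",
                        " its bounding box (expected 0.5-0.95)"), frac))
  cx <- mean(idx[, 2]); cy <- mean(idx[, 1])
  # principal axis of pixel coordinates; x right, y down -> report the
  # screen-CCW angle (positive = right end tilted up)
  X <- cbind(idx[, 2] - cx, idx[, 1] - cy)
  cv <- crossprod(X) / nrow(X)
  if (abs(cv[1, 1] - cv[2, 2]) < 1e-9 && abs(cv[1, 2]) < 1e-9) {
    ang <- 0 # circular mask: declare the x axis the major axis
  } else {
    ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
    ang <- atan2(-ev[2], ev[1]) * 180 / pi
    if (ang <= -90) ang <- ang + 180
    if (ang > 90) ang <- ang - 180
  }
  structure(list(mask = m, bbox = bbox,
                 height_px = as.integer(diff(rs) + 1L),
                 width_px = as.integer(diff(cs) + 1L),
                 centroid = c(x = cx, y = cy),
                 angle_deg = ang),
            class = "embryo_mask")
}

#' Align an embryo record to the canonical frame
#'
#' Rotates all registered images (and the mask, identically) so the mask's
#' principal axis is horizontal, crops to the mask bounding box plus a fixed
#' margin, and mirrors horizontally when the anterior pole is on the right.
#' Bilinear interpolation for images, nearest-neighbour for the mask. The
#' membrane image, being unregistered, is passed through untouched.
#'
#' @param record An [embryo_record].
#' @param mask An [embryo_mask] computed from the same record.
#' @param anterior_on_left Whether the anterior pole is already on the left
#'   (supplied as metadata; `FALSE` triggers a horizontal mirror).
#' @param margin_px Crop margin around the mask bounding box (default 10).
#' @return List with `record` (aligned) and `mask` (aligned `embryo_mask`).
#' @export
align_record <- function(record, mask, anterior_on_left = TRUE,
                         margin_px = 10) {
  stopifnot(inherits(record, "embryo_record"), inherits(mask, "embryo_mask"))
  d <- dim(record$images[["_ch00"]])
  if (!all(dim(mask$mask) == d[1:2]))
    stop("registration error: mask and image dimensions differ")
  ang <- mask$angle_deg
  ctr <- unname(mask$centroid)

  rot_mask <- if (abs(ang) > 1e-12)
    rotate_raster(mask$mask, -ang, ctr, "nearest", fill = 0) else mask$mask
  new_imgs <- record$images
  for (sfx in names(new_imgs)) {
    if (sfx == "_memb_ch00") next
    if (abs(ang) > 1e-12)
      new_imgs[[sfx]] <- rotate_raster(new_imgs[[sfx]], -ang, ctr,
                                       "bilinear", fill = 0)
  }
  am <- as_embryo_mask(rot_mask, check = FALSE)
  r1 <- am$bbox["r1"] - margin_px; r2 <- am$bbox["r2"] + margin_px
  c1 <- am$bbox["c1"] - margin_px; c2 <- am$bbox["c2"] + margin_px
  rot_mask <- crop_raster(rot_mask, r1, r2, c1, c2)
  for (sfx in names(new_imgs)) {
    if (sfx == "_memb_ch00") next
    new_imgs[[sfx]] <- crop_raster(new_imgs[[sfx]], r1, r2, c1, c2)
  }
  if (!anterior_on_left) {
    rot_mask <- mirror_raster(rot_mask)
    for (sfx in names(new_imgs)) {
      if (sfx == "_memb_ch00") next
      new_imgs[[sfx]] <- mirror_raster(new_imgs[[sfx]])
    }
  }
  out_rec <- record
  out_rec$images <- new_imgs
  list(record = out_rec, mask = as_embryo_mask(rot_mask))
}
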