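# Profiles: average RGB along the 10%-strip, unmix stain intensity, and map
# pixel x to % embryo length (%EL; 0 = anterior pole, 100 = posterior).

#' Extract the averaged RGB profile along the strip
#'
#' For each integer x along the midline spline, the column of pixels
#' perpendicular to the local spline tangent (length = strip height,
#' centred on the spline point, nearest-pixel sampling at unit spacing) is
#' averaged per channel. Column pixels falling outside the image are
#' dropped from the mean.
#'
#' @param bright_field Aligned bright-field raster (`[row, col, 3]`, 0--255).
#' @param strip A [strip_band].
#' @return An `expression_profile` data frame with columns `x`, `R`, `G`,
#'   `B`; attributes `channel` and `gene` unset until unmixing.
#' @export
extract_rgb_profile <- function(bright_field, strip) {
  stopifnot(inherits(strip, "strip_band"), length(dim(bright_field)) == 3L)
  d <- dim(bright_field)
  xs <- seq(ceiling(min(strip$spline$knots$x)),
            floor(max(strip$spline$knots$x)))
  out <- matrix(NA_real_, length(xs), 3)
  any_in <- FALSE
  for (i in seq_along(xs)) {
    col <- strip_column(strip, xs[i])
    r <- round(col$y); c <- round(col$x)
    ok <- r >= 1 & r <= d[1] & c >= 1 & c <= d[2]
    if (!any(ok)) next
    any_in <- TRUE
    for (k in 1:3) out[i, k] <- mean(bright_field[cbind(r[ok], c[ok], k)])
  }
  if (!any_in) stop("strip lies entirely outside the image")
  prof <- data.frame(x = xs, R = out[, 1], G = out[, 2], B = out[, 3])
  prof <- prof[stats::complete.cases(prof), ]
  rownames(prof) <- NULL
  class(prof) <- c("expression_profile", "data.frame")
  prof
}

#' Unmix NBT/BCIP (purple) stain intensity
#'
#' The purple reaction product absorbs the red channel, so stain intensity
#' is the inverse red channel: `intensity = 255 - R`. Green and blue are
#' ignored (blue carries a signal similar to red but with a weaker
#' signal-to-background ratio).
#'
#' @param profile An `expression_profile` with RGB columns.
#' @return The profile with an `intensity` column and `channel = "purple"`.
#' @export
unmix_nbt_bcip <- function(profile) {
  stopifnot(all(c("R", "G", "B") %in% names(profile)))
  profile$intensity <- 255 - profile$R
  attr(profile, "channel") <- "purple"
  profile
}

#' Unmix FastRed (red) stain intensity
#'
#' FastRed stain depresses green relative to red, so the red-minus-green
#' difference isolates the stain from both the blue component of any
#' NBT/BCIP co-stain and the yellow-like background of unstained tissue.
#' Default mode: `intensity = clamp(R - G, 0, 255)` (the subtraction itself
#' yields a stain-positive signal). The alternative `literal_invert` mode
#' additionally inverts: `intensity = 255 - (R - G)`.
#'
#' @param profile An `expression_profile` with RGB columns.
#' @param mode `"subtract"` (default) or `"literal_invert"`.
#' @return The profile with an `intensity` column and `channel = "red"`.
#' @export
unmix_fastred <- function(profile, mode = c("subtract", "literal_invert")) {
  mode <- match.arg(mode)
  stopifnot(all(c("R", "G", "B") %in% names(profile)))
  diffRG <- profile$R - profile$G
  profile$intensity <- switch(mode,
    subtract = pmin(pmax(diffRG, 0), 255),
    literal_invert = pmin(pmax(255 - diffRG, 0), 255))
  attr(profile, "channel") <- "red"
  profile
}

# Dispatch on the channel colour name used in the boundary tables.
unmix_profile <- function(profile, channel,
                          fastred_mode = "subtract") {
  switch(channel,
         purple = unmix_nbt_bcip(profile),
         red = unmix_fastred(profile, fastred_mode),
         stop("unknown channel '", channel, "' (expected purple or red)"))
}

#' Map profile positions to % embryo length
#'
#' Affine map of pixel x onto the A--P axis using the aligned mask's
#' horizontal extremes: `%EL = 100 * (x - x_min) / (x_max - x_min)`.
#'
#' @param profile An `expression_profile`.
#' @param mask The aligned [embryo_mask].
#' @return The profile with a `pct_el` column.
#' @export
to_percent_el <- function(profile, mask) {
  stopifnot(inherits(mask, "embryo_mask"))
  x_min <- mask$bbox[["c1"]]; x_max <- mask$bbox[["c2"]]
  if (x_max <= x_min) stop("degenerate mask: zero horizontal extent")
  profile$pct_el <- 100 * (profile$x - x_min) / (x_max - x_min)
  attr(profile, "el_span") <- c(x_min = x_min, x_max = x_max)
  profile
}

# %EL <-> pixel conversions for a profile that has been through
# to_percent_el (used when reporting boundary positions).
pct_el_of_x <- function(profile, x) {
  sp <- attr(profile, "el_span")
  if (is.null(sp)) stop("profile has no %EL mapping; call to_percent_el first")
  100 * (x - sp["x_min"]) / (sp["x_max"] - sp["x_min"])
}

#' Write / read a profile data file
#'
#' Plain-text format, one line per sample, whitespace-separated columns
#' `x R G B intensity` with a `#`-prefixed header line.
#'
#' @param profile Profile with an `intensity` column.
#' @param path Output path (`<id>_prof.dat` in the batch layout).
#' @return `path` invisibly (writer); the profile data frame (reader).
#' @export
write_profile_dat <- function(profile, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("# x R G B intensity", con, sep = "\n")
  writeLines(sprintf("%d %.4f %.4f %.4f %.4f", profile$x, profile$R,
                     profile$G, profile$B, profile$intensity), con, sep = "\n")
  invisible(path)
}

#' @rdname write_profile_dat
#' @export
read_profile_dat <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("x", "R", "G", "B", "intensity"))
  class(df) <- c("expression_profile", "data.frame")
  df
}
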