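# Staging: cleavage cycle (C1-C14A) from the nuclear counterstain, and time
# class (T1-T8) within cycle 14A from membrane morphology.
#
# Nuclei divide synchronously during cleavage, so the nuclear count doubles
# each cycle: a cycle-c embryo carries 2^(c-1) nuclei. Counting nuclei and
# rounding log2 to the nearest integer (i.e. classing at geometric midpoints
# between successive powers of two) therefore recovers the cycle.

#' The blastoderm staging timetable
#'
#' Cycle durations in minutes. Cycles up to C9 last roughly 10 min each;
#' C10--C14A last 13, 11, 14, 23 and 58 min respectively. C14A is further
#' subdivided into eight equal time classes (T1--T8) of 58/8 = 7.25 min.
#'
#' @return A list with `durations_min` (named vector, C1..C14A),
#'   `n_time_classes` (8), `time_class_min` (7.25) and `labels`
#'   (the 21 valid stage labels C1..C13, C14_T1..C14_T8, in order).
#' @export
staging_timetable <- function() {
  durations <- c(rep(10, 9), 13, 11, 14, 23, 58)
  names(durations) <- c(paste0("C", 1:13), "C14A")
  labels <- c(paste0("C", 1:13), paste0("C14_T", 1:8))
  list(
    durations_min = durations,
    n_time_classes = 8L,
    time_class_min = durations[["C14A"]] / 8,
    labels = labels
  )
}

#' Parse or build a stage label
#'
#' Valid labels are `C1`..`C13` and `C14_T1`..`C14_T8`; the time-class
#' subdivision exists only within cycle 14A.
#'
#' @param label Stage label string.
#' @return A `time_class` object: list with `label`, `cycle` (1--14) and
#'   `subclass` (1--8, or `NA` outside C14).
#' @export
time_class <- function(label) {
  labels <- staging_timetable()$labels
  if (!is.character(label) || length(label) != 1L || !(label %in% labels))
    stop("invalid stage label '", label, "'; valid labels are C1..C13, C14_T1..C14_T8")
  if (grepl("^C14_T", label)) {
    sub <- as.integer(sub("^C14_T", "", label))
    out <- list(label = label, cycle = 14L, subclass = sub)
  } else {
    out <- list(label = label, cycle = as.integer(sub("^C", "", label)),
                subclass = NA_integer_)
  }
  structure(out, class = "time_class")
}

#' Expected nucleus count for a cleavage cycle
#'
#' @param cycle Integer cycle 1--14.
#' @return `2^(cycle - 1)`.
#' @export
nuclei_for_cycle <- function(cycle) {
  stopifnot(cycle >= 1, cycle <= 14)
  2^(cycle - 1)
}

#' Assign a cleavage cycle from a nucleus count
#'
#' Under the doubling model the count at cycle c is 2^(c-1); class
#' boundaries sit at the geometric midpoints between successive powers of
#' two, i.e. `cycle = clamp(round(log2(n)) + 1, 1, 14)`.
#'
#' @param n_nuclei Positive nucleus count.
#' @return Integer cycle in 1--14.
#' @export
assign_cycle <- function(n_nuclei) {
  if (!is.numeric(n_nuclei) || length(n_nuclei) != 1L || is.na(n_nuclei) ||
      n_nuclei <= 0)
    stop("n_nuclei must be a single positive number")
  as.integer(min(14, max(1, round(log2(n_nuclei)) + 1)))
}

#' Assign a C14A time class from membrane invagination depth
#'
#' Membranisation progresses through cycle 14A; the depth fraction of the
#' membrane front (0 = not started, 1 = complete) indexes the eight equal
#' time classes: `subclass = min(8, floor(depth * 8) + 1)`.
#'
#' @param depth Invagination depth fraction in `[0, 1]`.
#' @return Integer subclass 1--8.
#' @export
assign_time_class <- function(depth) {
  if (!is.numeric(depth) || length(depth) != 1L || is.na(depth) ||
      depth < 0 || depth > 1)
    stop("membrane invagination depth must be a single value in [0, 1]")
  as.integer(min(8, floor(depth * 8) + 1))
}

#' Count nuclei in a nuclear-counterstain image
#'
#' Band-pass style detection: light Gaussian smoothing followed by
#' local-maximum detection (3x3 neighbourhood) above an intensity threshold,
#' restricted to the embryo mask. Plateau maxima are merged by connected
#' components so each nucleus is counted once.
#'
#' @param nuc Nuclear image (matrix or RGB array, 0--255), aligned with `mask`.
#' @param mask An [embryo_mask] object (or binary matrix) aligned with `nuc`.
#' @param threshold_frac Fraction of the image maximum below which peaks are
#'   ignored (default 0.35).
#' @param sigma Gaussian smoothing sd in pixels (default 0.7).
#' @return Integer nucleus count.
#' @export
count_nuclei <- function(nuc, mask, threshold_frac = 0.35, sigma = 0.7) {
  g <- raster_grey(nuc)
  m <- if (inherits(mask, "embryo_mask")) mask$mask else mask
  stopifnot(all(dim(g) == dim(m)))
  mx <- max(g)
  if (mx < 10) stop("nuclear image appears blank: uncountable")
  if (mean(g > 0.98 * 255) > 0.5) stop("nuclear image saturated: uncountable")
  gs <- gauss_smooth(g, sigma)
  peaks <- (dilate3(gs) == gs) & gs > threshold_frac * max(gs) & (m > 0)
  if (!any(peaks)) stop("no nuclei detected: uncountable")
  lab <- EBImage::bwlabel(peaks * 1L)
  as.integer(max(lab))
}

# Separable Gaussian smoothing of a matrix.
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  sm_cols <- apply(m, 2, function(col) stats::filter(c(rep(col[1], r), col, rep(col[length(col)], r)), k)[(r + 1):(r + length(col))])
  t(apply(sm_cols, 1, function(row) stats::filter(c(rep(row[1], r), row, rep(row[length(row)], r)), k)[(r + 1):(r + length(row))]))
}

#' Measure membrane-front depth from a membrane-morphology image
#'
#' The synthetic membrane rendering encodes progression of cellularisation
#' as a dark front advancing from the top of the frame; depth is the
#' fraction of rows darker than mid-grey. On real data the depth (or the
#' time class itself) is supplied by the curator instead.
#'
#' @param memb Membrane image (matrix or RGB array, 0--255).
#' @return Depth fraction in `[0, 1]`.
#' @export
membrane_depth <- function(memb) {
  g <- raster_grey(memb)
  mean(rowMeans(g) < 128)
}

#' Stage an embryo from its nuclear and membrane images
#'
#' Combines [count_nuclei()], [assign_cycle()] and, within cycle 14,
#' [membrane_depth()] + [assign_time_class()]. An explicit
#' `override_label` (curator metadata) always wins.
#'
#' @param nuc Nuclear image. @param memb Membrane image (may be `NULL`
#'   outside C14). @param mask [embryo_mask] aligned with `nuc`.
#' @param override_label Optional curator-supplied stage label.
#' @return A [time_class] object.
#' @export
stage_embryo <- function(nuc, memb, mask, override_label = NULL) {
  if (!is.null(override_label)) return(time_class(override_label))
  n <- count_nuclei(nuc, mask)
  cyc <- assign_cycle(n)
  if (cyc < 14L) return(time_class(paste0("C", cyc)))
  if (is.null(memb)) stop("cycle-14 embryo needs a membrane image or an override label")
  sub <- assign_time_class(membrane_depth(memb))
  time_class(paste0("C14_T", sub))
}
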