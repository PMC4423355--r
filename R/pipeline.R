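# Orchestration: configuration object and the end-to-end batch pipeline
# (images -> mask -> alignment -> midline strip -> profile -> boundary
# fits -> staging -> CSV tables), with per-embryo error isolation and a
# structured run log.

#' Pipeline configuration
#'
#' Collects the tunable constants of the quantification pipeline. The
#' printed pipeline constants (10% strip, five knots) are the defaults;
#' everything else is implementation configuration.
#'
#' @param strip_fraction Strip height as a fraction of mask height,
#'   in `(0, 0.5]` (default 0.10).
#' @param knot_count Number of midline knots, >= 3 (default 5; the table
#'   schema stores exactly 5).
#' @param fastred_mode FastRed unmixing mode, `"subtract"` or
#'   `"literal_invert"` (see [unmix_fastred()]).
#' @param min_amplitude Boundary-detection amplitude threshold in
#'   intensity units (default 30).
#' @param crop_margin_px Crop margin around the mask bounding box
#'   (default 10).
#' @param seed Base random seed for stochastic steps (default 1).
#' @param catalogue_path Optional path to a boundary-catalogue CSV
#'   replacing the shipped default.
#' @return A `pipeline_config` object (list).
#' @export
pipeline_config <- function(strip_fraction = 0.10, knot_count = 5L,
                            fastred_mode = c("subtract", "literal_invert"),
                            min_amplitude = 30, crop_margin_px = 10,
                            seed = 1L, catalogue_path = NULL) {
  fastred_mode <- match.arg(fastred_mode)
  stopifnot(strip_fraction > 0, strip_fraction <= 0.5, knot_count >= 3)
  structure(list(strip_fraction = strip_fraction,
                 knot_count = as.integer(knot_count),
                 fastred_mode = fastred_mode,
                 min_amplitude = min_amplitude,
                 crop_margin_px = crop_margin_px, seed = as.integer(seed),
                 catalogue_path = catalogue_path),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a key-value file
#'
#' Flat `key = value` (or `key: value`) text file; keys matching
#' [pipeline_config()] arguments override the defaults.
#'
#' @param path Config file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[=:]", perl = TRUE)
  args <- list()
  for (p in kv) {
    key <- trimws(p[1]); val <- trimws(paste(p[-1], collapse = ":"))
    num <- suppressWarnings(as.numeric(val))
    args[[key]] <- if (!is.na(num)) num else val
  }
  known <- names(formals(pipeline_config))
  do.call(pipeline_config, args[names(args) %in% known])
}

#' Quantify one embryo record
#'
#' Runs the per-embryo chain: DIC mask, alignment, skeleton midline, five
#' knots, 10% strip, RGB profile, stain unmixing, %EL mapping, boundary
#' detection + clamped-spline fits, catalogue ID assignment, and staging.
#'
#' @param record An [embryo_record] (raw, unaligned).
#' @param config A [pipeline_config()].
#' @param anterior_on_left Orientation metadata (default `TRUE`).
#' @param stage_override Optional curator stage label (bypasses image
#'   staging).
#' @param knot_override Optional 5 manual midline knots.
#' @return List: `mask` (aligned), `strip`, `profile`, `fits`, `stage`
#'   (a [time_class]), `record` (aligned).
#' @export
quantify_embryo <- function(record, config = pipeline_config(),
                            anterior_on_left = TRUE, stage_override = NULL,
                            knot_override = NULL) {
  mask0 <- compute_mask(record$images[["_dic_ch00"]])
  al <- align_record(record, mask0, anterior_on_left = anterior_on_left,
                     margin_px = config$crop_margin_px)
  path <- skeleton_midline(al$mask)
  spline <- place_knots(path, al$mask, override = knot_override)
  strip <- make_strip(spline, al$mask, config$strip_fraction)
  prof <- extract_rgb_profile(al$record$images[["_ch00"]], strip)
  prof <- unmix_profile(prof, record$channel, config$fastred_mode)
  prof <- to_percent_el(prof, al$mask)
  wins <- detect_boundary_windows(prof, config$min_amplitude)
  fits <- lapply(wins, function(w) fit_clamped_boundary(prof, w))
  catalogue <- boundary_catalogue(config$catalogue_path)
  fits <- assign_boundary_ids(fits, record$gene, catalogue)
  stage <- stage_embryo(al$record$images[["_nuc_ch00"]],
                        al$record$images[["_memb_ch00"]], al$mask,
                        override_label = stage_override)
  list(mask = al$mask, strip = strip, profile = prof, fits = fits,
       stage = stage, record = al$record)
}

#' Run the pipeline over a batch directory
#'
#' Processes every embryo in one batch of the standard layout: reads the
#' four acquisition PNGs, quantifies each embryo, writes the intermediate
#' rasters (`_embmsk`, `_band`, `_stband`) and `_prof.dat`, and emits the
#' two batch CSV tables (`*_timeclasses_bands.csv`, `*_boundary_data.csv`).
#' Per-embryo failures are logged and skipped; the run errors only if more
#' than half of a batch fails.
#'
#' @param root Directory containing the `ish/` (or `RNAi/`) tree.
#' @param batch Batch id string or [batch_id].
#' @param config A [pipeline_config()].
#' @param rnai Whether the batch lives under the RNAi tree.
#' @param stage_overrides Optional named character vector
#'   (embryo id -> stage label).
#' @return List: `timeclasses` and `boundaries` (the two tables),
#'   `log` (per-embryo status data frame), `failed` (ids).
#' @export
run_pipeline <- function(root, batch, config = pipeline_config(),
                         rnai = FALSE, stage_overrides = NULL) {
  if (is.character(batch)) batch <- parse_batch_id(batch)
  proc <- file.path(root, dirname(layout_paths(batch, "001", "_ch00", rnai)))
  if (!dir.exists(proc)) stop("batch directory not found: ", proc)
  files <- list.files(proc)
  ids <- sort(unique(regmatches(files, regexpr("^[0-9]{3}", files))))
  if (length(ids) == 0) stop("no embryos found in ", proc)

  manifest <- NULL
  mpath <- file.path(proc, "manifest.csv")
  if (file.exists(mpath))
    manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)

  tc_rows <- list(); bd_rows <- list(); log_rows <- list()
  prefix <- if (rnai) "RNAi" else "wt"
  for (id in ids) {
    t0 <- proc.time()[["elapsed"]]
    status <- "ok"; message_txt <- ""
    res <- tryCatch({
      imgs <- lapply(stats::setNames(nm = c("_ch00", "_dic_ch00", "_nuc_ch00",
                                            "_memb_ch00")), function(sfx)
        read_raster_png(file.path(root, layout_paths(batch, id, sfx, rnai))))
      gene <- batch$stain
      channel <- "purple"
      stage_ov <- stage_overrides[[id]]
      if (!is.null(manifest)) {
        mrow <- manifest[manifest$embryo_id == as.integer(id) |
                           manifest$embryo_id == id, , drop = FALSE]
        if (nrow(mrow) == 1) {
          gene <- mrow$gene
          channel <- stain_channel(mrow$stain)
        }
      }
      rec <- embryo_record(id, format(batch), imgs, gene, channel,
                           is_rnai = rnai)
      q <- quantify_embryo(rec, config, stage_override = stage_ov)

      write_raster_png(q$mask$mask * 255,
                       file.path(root, layout_paths(batch, id, "_embmsk", rnai)))
      write_raster_png(render_strip_overlay(q$mask$mask * 255, q$strip),
                       file.path(root, layout_paths(batch, id, "_band", rnai)))
      write_raster_png(render_strip_overlay(q$record$images[["_ch00"]],
                                            q$strip),
                       file.path(root, layout_paths(batch, id, "_stband", rnai)))
      write_profile_dat(q$profile,
                        file.path(root, layout_paths(batch, id, "_prof.dat",
                                                     rnai)))
      embryo_path <- paste0(format(batch), "/proc/", id)
      k <- q$strip$spline$knots
      tc <- data.frame(embryo = embryo_path, timeclass = q$stage$label,
                       spline_height = q$strip$height_px,
                       t(stats::setNames(k$x, paste0("spline_x", 1:5))),
                       t(stats::setNames(k$y, paste0("spline_y", 1:5))),
                       check.names = FALSE, stringsAsFactors = FALSE)
      assigned <- Filter(function(f) isTRUE(f$assigned), q$fits)
      bd <- if (length(assigned))
        boundary_fits_to_rows(assigned, embryo_path, channel) else NULL
      list(tc = tc, bd = bd)
    }, error = function(e) {
      status <<- "failed"; message_txt <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) {
      tc_rows[[id]] <- res$tc
      if (!is.null(res$bd)) bd_rows[[id]] <- res$bd
    }
    log_rows[[id]] <- data.frame(
      embryo_id = id, status = status, message = message_txt,
      seconds = round(proc.time()[["elapsed"]] - t0, 2),
      stringsAsFactors = FALSE)
  }
  log <- do.call(rbind, log_rows); rownames(log) <- NULL
  failed <- log$embryo_id[log$status == "failed"]
  if (length(failed) > length(ids) / 2)
    stop("more than half the batch failed (", length(failed), "/",
         length(ids), "); first error: ",
         log$message[log$status == "failed"][1])

  timeclasses <- do.call(rbind, tc_rows); rownames(timeclasses) <- NULL
  boundaries <- if (length(bd_rows)) do.call(rbind, bd_rows) else
    stats::setNames(data.frame(matrix(ncol = 11, nrow = 0)), BOUNDARY_COLS)
  rownames(boundaries) <- NULL
  write_timeclasses_bands(timeclasses,
                          file.path(root, paste0(prefix,
                                                 "_timeclasses_bands.csv")))
  write_boundary_data(boundaries,
                      file.path(root, paste0(prefix, "_boundary_data.csv")))
  list(timeclasses = timeclasses, boundaries = boundaries, log = log,
       failed = failed)
}
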