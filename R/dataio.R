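# Data I/O: the batch directory layout, PNG suffix scheme and the three
# CSV table schemas, with validating readers and byte-deterministic
# writers (comma separator, LF line endings, headers exactly as deposited:
# note "boundary id" with a space in the integrated table but
# "boundary_id" underscored in the per-embryo boundary tables).

IMAGE_SUFFIXES <- c("_ch00", "_dic_ch00", "_nuc_ch00", "_memb_ch00",
                    "_embmsk", "_band", "_stband")
ALL_SUFFIXES <- c(IMAGE_SUFFIXES, "_prof.dat")

#' Batch identifier
#'
#' Batches are named `species_stain_date`, e.g. `ma_gt_260911`: species
#' token, gene/stain token, date as DDMMYY.
#'
#' @param species Species token (e.g. `"ma"`).
#' @param stain Gene abbreviation token.
#' @param date DDMMYY date token.
#' @return A `batch_id` object; `format()` yields the joined string.
#' @export
batch_id <- function(species, stain, date) {
  stopifnot(grepl("^[A-Za-z0-9]+$", species), grepl("^[A-Za-z0-9]+$", stain),
            grepl("^[0-9]{6}$", date))
  structure(list(species = species, stain = stain, date = date),
            class = "batch_id")
}

#' @export
format.batch_id <- function(x, ...) paste(x$species, x$stain, x$date,
                                          sep = "_")

#' @rdname batch_id
#' @param id Batch id string to parse.
#' @export
parse_batch_id <- function(id) {
  parts <- strsplit(id, "_", fixed = TRUE)[[1]]
  if (length(parts) != 3L)
    stop("batch id must be 'species_stain_date', got '", id, "'")
  batch_id(parts[1], parts[2], parts[3])
}

#' Path of one on-disk artifact in the batch layout
#'
#' Wild-type batches live under `ish/megaselia/<batch>/proc/`, RNAi
#' batches under `RNAi/megaselia/<batch>/proc/`. Image suffixes get a
#' `.png` extension; the profile suffix `_prof.dat` is a text file.
#' E.g. `layout_paths(batch, "001", "_ch00")` gives
#' `ish/megaselia/ma_gt_260911/proc/001_ch00.png`.
#'
#' @param batch A [batch_id] (or its string form).
#' @param embryo_id Zero-padded 3-digit embryo id.
#' @param suffix One of `_ch00`, `_dic_ch00`, `_nuc_ch00`, `_memb_ch00`,
#'   `_embmsk`, `_band`, `_stband`, `_prof.dat`.
#' @param rnai Whether the batch is RNAi-treated (roots the tree at
#'   `RNAi/` instead of `ish/`).
#' @return Relative path with forward slashes.
#' @export
layout_paths <- function(batch, embryo_id, suffix, rnai = FALSE) {
  if (is.character(batch)) batch <- parse_batch_id(batch)
  if (!suffix %in% ALL_SUFFIXES)
    stop("unknown suffix '", suffix, "'; valid: ",
         paste(ALL_SUFFIXES, collapse = ", "))
  fname <- if (suffix == "_prof.dat") paste0(embryo_id, suffix) else
    paste0(embryo_id, suffix, ".png")
  paste(if (rnai) "RNAi" else "ish", "megaselia", format(batch), "proc",
        fname, sep = "/")
}

#' @rdname layout_paths
#' @param path A path produced by `layout_paths()`.
#' @return For `parse_layout_path()`: list with `batch`, `embryo_id`,
#'   `suffix`, `rnai`.
#' @export
parse_layout_path <- function(path) {
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  if (length(parts) != 5L || parts[2] != "megaselia" || parts[4] != "proc" ||
      !parts[1] %in% c("ish", "RNAi"))
    stop("path does not follow the batch layout: ", path)
  fname <- parts[5]
  sfx <- ALL_SUFFIXES[vapply(ALL_SUFFIXES, function(s) {
    tail <- if (s == "_prof.dat") s else paste0(s, ".png")
    endsWith(fname, tail)
  }, logical(1))]
  if (length(sfx) == 0) stop("unknown suffix in file name: ", fname)
  sfx <- sfx[which.max(nchar(sfx))]
  tail <- if (sfx == "_prof.dat") sfx else paste0(sfx, ".png")
  list(batch = parse_batch_id(parts[3]),
       embryo_id = substr(fname, 1, nchar(fname) - nchar(tail)),
       suffix = sfx, rnai = parts[1] == "RNAi")
}

# ---- CSV schemas ----------------------------------------------------------

TIMECLASS_COLS <- c("embryo", "timeclass", "spline_height",
                    paste0("spline_x", 1:5), paste0("spline_y", 1:5))
BOUNDARY_COLS <- c("embryo", "boundary_id", "facing", "gene", "channel",
                   paste0("boundary_x", 1:3), paste0("boundary_y", 1:3))
INTEGRATED_COLS <- c("gene", "timeclass", "boundary id", "mean", "median",
                     "standard deviation", "MAD")

# Deterministic numeric formatting: plain decimal, up to 15 significant
# digits (round-trips through a double losslessly).
fmt_num <- function(v) {
  ifelse(v == round(v) & abs(v) < 1e15,
         sprintf("%d", as.integer(round(v))),
         format(v, trim = TRUE, scientific = FALSE, digits = 15))
}

write_csv_lines <- function(lines, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

stop_row <- function(file_kind, i, msg)
  stop(sprintf("%s line %d: %s", file_kind, i + 1L, msg), call. = FALSE)

#' Read / write the time-classes-and-bands table
#'
#' 13 fixed columns: `embryo` (id + directory path), `timeclass` (stage
#' label), `spline_height` (strip height in pixels) and the five midline
#' knot coordinates `spline_x1..x5`, `spline_y1..y5` (pixels, origin
#' upper-left). Writing then re-reading a canonical file is
#' byte-identical.
#'
#' @param path CSV path.
#' @param rows Data frame with the 13 schema columns.
#' @return Reader: validated data frame. Writer: `path`, invisibly.
#' @export
read_timeclasses_bands <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(names(df), TIMECLASS_COLS))
    stop("timeclasses_bands: expected columns ",
         paste(TIMECLASS_COLS, collapse = ","))
  labels <- staging_timetable()$labels
  for (i in seq_len(nrow(df))) {
    if (!df$timeclass[i] %in% labels)
      stop_row("timeclasses_bands", i,
               paste0("invalid timeclass '", df$timeclass[i], "'"))
    xs <- as.numeric(df[i, paste0("spline_x", 1:5)])
    if (anyNA(xs) || is.unsorted(xs, strictly = TRUE))
      stop_row("timeclasses_bands", i,
               "spline_x1..x5 must be numeric and strictly increasing")
    if (anyNA(as.numeric(df[i, c("spline_height", paste0("spline_y", 1:5))])))
      stop_row("timeclasses_bands", i, "non-numeric coordinate")
  }
  df
}

#' @rdname read_timeclasses_bands
#' @export
write_timeclasses_bands <- function(rows, path) {
  stopifnot(identical(names(rows)[seq_along(TIMECLASS_COLS)], TIMECLASS_COLS))
  num <- vapply(seq_len(nrow(rows)), function(i)
    paste(fmt_num(as.numeric(rows[i, TIMECLASS_COLS[-(1:2)]])),
          collapse = ","), character(1))
  body <- if (nrow(rows)) paste(rows$embryo, rows$timeclass, num, sep = ",")
          else character(0)
  write_csv_lines(c(paste(TIMECLASS_COLS, collapse = ","), body), path)
}

#' Read / write the per-embryo boundary table
#'
#' 11 fixed columns: `embryo`, `boundary_id`, `facing`
#' (anterior/posterior), `gene`, `channel` (purple/red), and the clamped
#' spline control points `boundary_x1..x3`, `boundary_y1..y3` (pixels,
#' origin at the upper-left corner of the profile graph, so y grows
#' downward).
#'
#' @param path CSV path.
#' @param rows Data frame with the 11 schema columns.
#' @return Reader: validated data frame. Writer: `path`, invisibly.
#' @export
read_boundary_data <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(names(df), BOUNDARY_COLS))
    stop("boundary_data: expected columns ",
         paste(BOUNDARY_COLS, collapse = ","))
  for (i in seq_len(nrow(df))) {
    if (!df$facing[i] %in% c("anterior", "posterior"))
      stop_row("boundary_data", i,
               paste0("invalid facing '", df$facing[i],
                      "' (must be anterior or posterior)"))
    if (!df$channel[i] %in% c("purple", "red"))
      stop_row("boundary_data", i,
               paste0("invalid channel '", df$channel[i],
                      "' (must be purple or red)"))
    xs <- as.numeric(df[i, paste0("boundary_x", 1:3)])
    if (anyNA(xs) || is.unsorted(xs, strictly = TRUE))
      stop_row("boundary_data", i,
               "boundary_x1..x3 must be numeric and strictly increasing")
    if (anyNA(as.numeric(df[i, paste0("boundary_y", 1:3)])))
      stop_row("boundary_data", i, "non-numeric coordinate")
  }
  df
}

#' @rdname read_boundary_data
#' @export
write_boundary_data <- function(rows, path) {
  stopifnot(identical(names(rows)[seq_along(BOUNDARY_COLS)], BOUNDARY_COLS))
  body <- if (nrow(rows)) vapply(seq_len(nrow(rows)), function(i)
    paste(rows$embryo[i], fmt_num(rows$boundary_id[i]), rows$facing[i],
          rows$gene[i], rows$channel[i],
          paste(fmt_num(as.numeric(rows[i, BOUNDARY_COLS[6:11]])),
                collapse = ","), sep = ","), character(1)) else character(0)
  write_csv_lines(c(paste(BOUNDARY_COLS, collapse = ","), body), path)
}

#' Read / write the integrated atlas table
#'
#' 7 fixed columns -- `gene`, `timeclass`, `boundary id` (header printed
#' with a space), `mean`, `median`, `standard deviation`, `MAD` -- all
#' positions in % embryo length. An optional trailing `n` column (group
#' size) can be emitted with `include_n = TRUE` and is accepted on read.
#'
#' @param path CSV path.
#' @param rows Data frame as produced by [aggregate_boundaries()].
#' @param include_n Emit the extra `n` column (default `FALSE`).
#' @return Reader: validated data frame (internal column names
#'   `boundary_id`, `standard_deviation`). Writer: `path`, invisibly.
#' @export
read_integrated <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  has_n <- identical(names(df), c(INTEGRATED_COLS, "n"))
  if (!has_n && !identical(names(df), INTEGRATED_COLS))
    stop("integrated table: expected columns ",
         paste(INTEGRATED_COLS, collapse = ","), " (optionally plus n)")
  labels <- staging_timetable()$labels
  for (i in seq_len(nrow(df))) {
    if (!df$timeclass[i] %in% labels)
      stop_row("integrated", i,
               paste0("invalid timeclass '", df$timeclass[i], "'"))
    if (anyNA(as.numeric(df[i, c("mean", "median", "standard deviation",
                                 "MAD")])))
      stop_row("integrated", i, "non-numeric statistic")
  }
  names(df)[names(df) == "boundary id"] <- "boundary_id"
  names(df)[names(df) == "standard deviation"] <- "standard_deviation"
  df
}

#' @rdname read_integrated
#' @export
write_integrated <- function(rows, path, include_n = FALSE) {
  internal <- c("gene", "timeclass", "boundary_id", "mean", "median",
                "standard_deviation", "MAD")
  stopifnot(all(internal %in% names(rows)))
  header <- paste(c(INTEGRATED_COLS, if (include_n) "n"), collapse = ",")
  body <- if (nrow(rows)) vapply(seq_len(nrow(rows)), function(i)
    paste(c(rows$gene[i], rows$timeclass[i], fmt_num(rows$boundary_id[i]),
            fmt_num(as.numeric(rows[i, c("mean", "median",
                                         "standard_deviation", "MAD")])),
            if (include_n) fmt_num(rows$n[i])),
          collapse = ","), character(1)) else character(0)
  write_csv_lines(c(header, body), path)
}

#' Validate a batch directory tree
#'
#' Walks every batch under `ish/megaselia` (and `RNAi/megaselia`) below
#' `root`, checks that each embryo id carries the four acquisition images,
#' and reports a structured per-embryo QC summary.
#'
#' @param root Directory containing the `ish/` (and/or `RNAi/`) tree.
#' @return Data frame: `batch`, `embryo_id`, `rnai`, `n_files`,
#'   `complete` (all four acquisition suffixes present), `missing`.
#' @export
validate_tree <- function(root) {
  acquisition <- c("_ch00", "_dic_ch00", "_nuc_ch00", "_memb_ch00")
  rows <- list()
  for (top in c("ish", "RNAi")) {
    base <- file.path(root, top, "megaselia")
    if (!dir.exists(base)) next
    for (bdir in list.dirs(base, recursive = FALSE)) {
      proc <- file.path(bdir, "proc")
      if (!dir.exists(proc)) next
      files <- list.files(proc)
      ids <- unique(sub("(_[a-z0-9_]+)?(\\.png|\\.dat)$", "",
                        sub("_prof\\.dat$", "", files)))
      ids <- unique(regmatches(files, regexpr("^[0-9]{3}", files)))
      for (id in ids) {
        present <- vapply(acquisition, function(s)
          paste0(id, s, ".png") %in% files, logical(1))
        rows[[length(rows) + 1]] <- data.frame(
          batch = basename(bdir), embryo_id = id, rnai = top == "RNAi",
          n_files = sum(startsWith(files, id)),
          complete = all(present),
          missing = paste(acquisition[!present], collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(batch = character(0), embryo_id = character(0),
                      rnai = logical(0), n_files = integer(0),
                      complete = logical(0), missing = character(0)))
  do.call(rbind, rows)
}
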