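# Integration: aggregate boundary positions across embryos into the
# per-gene, per-time-class atlas. Positions are summarised by both the
# arithmetic mean / sample SD and the median / MAD (unscaled: the raw
# median of absolute deviations from the median, in % embryo length).

#' Aggregate boundary fits into the integrated atlas
#'
#' Groups by `(gene, timeclass, boundary_id)` and reports arithmetic mean,
#' median, sample standard deviation (n-1 denominator) and unscaled MAD of
#' the A--P position in %EL, plus the group size `n`. Single-member groups
#' report 0 dispersion. Output rows are ordered by gene, then time class
#' (staging order), then boundary id.
#'
#' @param fits Data frame with columns `gene`, `timeclass`, `boundary_id`,
#'   `position_pct_el`, and optionally `is_rnai`.
#' @param force Aggregate RNAi-tagged fits anyway (see
#'   [skip_integration_for_rnai()]).
#' @return Data frame of `integrated_boundary` rows: `gene`, `timeclass`,
#'   `boundary_id`, `mean`, `median`, `standard_deviation`, `MAD`, `n`.
#' @export
aggregate_boundaries <- function(fits, force = FALSE) {
  need <- c("gene", "timeclass", "boundary_id", "position_pct_el")
  stopifnot(all(need %in% names(fits)))
  skip_integration_for_rnai(fits, force = force)
  miss <- is.na(fits$position_pct_el)
  if (any(miss)) {
    warning(sum(miss), " fit(s) without a position excluded from integration")
    fits <- fits[!miss, , drop = FALSE]
  }
  if (nrow(fits) == 0) stop("no fits with positions to integrate")
  tc_order <- staging_timetable()$labels
  fits$timeclass <- factor(fits$timeclass, levels = tc_order)
  if (anyNA(fits$timeclass)) stop("invalid timeclass label(s) in fits")
  groups <- split(fits, list(fits$gene, fits$timeclass, fits$boundary_id),
                  drop = TRUE)
  rows <- lapply(groups, function(g) {
    x <- g$position_pct_el
    data.frame(gene = g$gene[1], timeclass = as.character(g$timeclass[1]),
               boundary_id = g$boundary_id[1],
               mean = mean(x),
               median = stats::median(x),
               standard_deviation = if (length(x) > 1) stats::sd(x) else 0,
               MAD = stats::mad(x, constant = 1),
               n = length(x), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, match(out$timeclass, tc_order),
                   out$boundary_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Guard against integrating RNAi-treated embryos
#'
#' Knock-down strength varies from embryo to embryo, so averaging boundary
#' positions across an RNAi batch is not meaningful; the atlas integrates
#' wild-type data only. RNAi-tagged fits are refused unless `force = TRUE`.
#'
#' @param fits Data frame of fits (column `is_rnai`, if present, marks
#'   RNAi-background embryos).
#' @param force Permit aggregation with a prominent warning.
#' @return `TRUE` invisibly if aggregation may proceed.
#' @export
skip_integration_for_rnai <- function(fits, force = FALSE) {
  rnai <- isTRUE(any(fits$is_rnai))
  if (rnai && !force)
    stop("fits include RNAi-treated embryos: knock-down variability makes ",
         "integrated boundary positions unreliable; pass force = TRUE to ",
         "aggregate anyway")
  if (rnai && force)
    warning("integrating RNAi-treated embryos on request; interpret ",
            "aggregate positions with caution")
  invisible(TRUE)
}
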