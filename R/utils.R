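# shared internal helpers

sv_types <- function() {
  c("DEL", "DUP", "INS", "INV", "CPX", "MCNV", "BND_UNRESOLVED", "CTX")
}

interval_types <- function() c("DEL", "DUP", "INV", "CPX", "MCNV")

#' Map a panel class to its gene group
#'
#' Panel classes are the ADME families (`NR`, `CYP`, `SLC`, `ABC`, `phase1`,
#' `phase2`, `adme_other`), the drug-target classes (`ion_channel`,
#' `membrane_receptor`, `enzyme`, `transporter`, `target_other`),
#' `olfactory`, or `none`.
#'
#' @param panel_class Character vector of panel class labels.
#' @return Character vector: `"ADME"`, `"drug_target"`, `"olfactory"` or
#'   `"none"`.
#' @export
#' @examples
#' panel_group(c("CYP", "ion_channel", "olfactory"))
panel_group <- function(panel_class) {
  adme <- c("NR", "CYP", "SLC", "ABC", "phase1", "phase2", "adme_other")
  target <- c("ion_channel", "membrane_receptor", "enzyme", "transporter",
              "target_other")
  out <- rep("none", length(panel_class))
  out[panel_class %in% adme] <- "ADME"
  out[panel_class %in% target] <- "drug_target"
  out[panel_class %in% "olfactory"] <- "olfactory"
  out
}

# intersection width of [s1,e1) and [s2,e2); 0 when disjoint
overlap_bp <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

# validate a 0-based half-open interval
check_interval <- function(chrom, start, end) {
  if (any(is.na(chrom)) || any(!nzchar(chrom))) {
    abort("`chrom` must be non-empty")
  }
  if (any(start >= end)) abort("interval must satisfy start < end")
  invisible(TRUE)
}

# GRanges from a 0-based half-open tibble (converted to 1-based closed)
as_granges0 <- function(df, chrom = "chrom", start = "start", end = "end") {
  GenomicRanges::GRanges(
    seqnames = df[[chrom]],
    ranges = IRanges::IRanges(start = df[[start]] + 1L, end = df[[end]])
  )
}

#' Format a proportion as a percentage
#'
#' Headline shares are rounded to the nearest integer (e.g. 14.7% of SVs
#' affecting exons is reported as "15%"); table cells keep one decimal.
#'
#' @param x Proportion in `[0, 1]`.
#' @param headline Round to the nearest integer percent?
#' @return Numeric percent value (not a string).
#' @export
#' @examples
#' percent_of(2198 / 14984)            # 14.7
#' percent_of(2198 / 14984, headline = TRUE)  # 15
percent_of <- function(x, headline = FALSE) {
  if (headline) round(100 * x) else round(100 * x, 1)
}

# attach / extend a stage log kept as an attribute on pipeline tables
add_log <- function(x, step, reason, n) {
  log <- attr(x, "pgx_log") %||%
    tibble(step = character(), reason = character(), n = integer())
  attr(x, "pgx_log") <- bind_rows(log, tibble(step = step, reason = reason,
                                              n = as.integer(n)))
  x
}

#' Retrieve the record-count log attached to a pipeline table
#'
#' Every stage that drops records tallies the removals by reason so that
#' input = retained + sum(removed) can be audited.
#'
#' @param x A table produced by a pgxsv stage.
#' @return A tibble with columns `step`, `reason`, `n`.
#' @export
pgx_log <- function(x) {
  attr(x, "pgx_log") %||%
    tibble(step = character(), reason = character(), n = integer())
}
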