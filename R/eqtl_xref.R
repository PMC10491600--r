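#' Read an SV-eQTL table
#'
#' TSV schema: `chrom`, `start`, `end` (0-based half-open), `sv_type`,
#' `gene`, `tissue`, `beta` (effect size; sign = direction of the expression
#' change), `bh_p` (Benjamini-Hochberg adjusted p, either in (0,1] or on the
#' -log10 scale via `p_scale = "neglog10"`).
#'
#' @param path TSV path.
#' @param p_scale `"p"` or `"neglog10"`.
#' @return Tibble with an `eqtl_id` column added and `bh_p` on the (0,1]
#'   scale plus `neglog10_bh` for reporting.
#' @export
read_eqtl_table <- function(path, p_scale = c("p", "neglog10")) {
  p_scale <- match.arg(p_scale)
  d <- readr::read_tsv(path, show_col_types = FALSE)
  if (p_scale == "neglog10") {
    d$neglog10_bh <- d$bh_p
    d$bh_p <- 10^(-d$bh_p)
  } else {
    d$neglog10_bh <- -log10(d$bh_p)
  }
  if (any(d$bh_p <= 0 | d$bh_p > 1)) abort("bh_p must lie in (0, 1]")
  d$eqtl_id <- paste0("eqtl_", seq_len(nrow(d)))
  as_tibble(d)
}

#' Match SV-eQTLs to cohort SVs by breakpoints and reciprocal overlap
#'
#' For every eQTL the nearest same-chromosome SV (by summed breakpoint
#' distance) is found. A match is "near" when both breakpoint offsets are at
#' most `near_bp`; it is "included" when the reciprocal overlap fraction
#' (intersection over the eQTL interval AND over the SV interval) exceeds
#' `min_overlap` (>99% by default). One-sided overlap would admit a tiny SV
#' inside a huge eQTL interval, so both sides are required. Insertion-type
#' pairs match by insertion-point distance only (overlap defined as 1 when
#' both offsets are within `near_bp`, otherwise 0). `same_type` records
#' whether the SV types agree; both criteria are reported separately.
#'
#' @param eqtls Tibble from [read_eqtl_table()].
#' @param svs An `sv_table` (or any tibble with `sv_id`, `chrom`, `start`,
#'   `end`, `sv_type`).
#' @param near_bp Breakpoint distance threshold in bp.
#' @param min_overlap Reciprocal overlap fraction that a match must exceed.
#' @return Tibble with one row per eQTL: `eqtl_id`, `sv_id` (NA when no SV
#'   shares the chromosome), `d_start`, `d_end`, `overlap`, `near`,
#'   `included`, `same_type`.
#' @export
match_eqtl <- function(eqtls, svs, near_bp = 100L, min_overlap = 0.99) {
  svs <- as_tibble(svs)
  rows <- lapply(seq_len(nrow(eqtls)), function(i) {
    e <- eqtls[i, ]
    cand <- svs[svs$chrom == e$chrom, ]
    if (nrow(cand) == 0) {
      return(tibble(eqtl_id = e$eqtl_id, sv_id = NA_character_,
                    d_start = NA_integer_, d_end = NA_integer_,
                    overlap = NA_real_, near = FALSE, included = FALSE,
                    same_type = FALSE))
    }
    ds <- abs(cand$start - e$start)
    de <- abs(cand$end - e$end)
    j <- order(ds + de, cand$sv_id)[1]
    sv <- cand[j, ]
    both_ins <- e$sv_type == "INS" && sv$sv_type == "INS"
    near <- ds[j] <= near_bp && de[j] <= near_bp
    ov <- if (both_ins) {
      if (near) 1 else 0
    } else {
      inter <- overlap_bp(e$start, e$end, sv$start, sv$end)
      min(inter / (e$end - e$start), inter / (sv$end - sv$start))
    }
    tibble(eqtl_id = e$eqtl_id, sv_id = sv$sv_id,
           d_start = ds[j], d_end = de[j], overlap = ov,
           near = near, included = ov > min_overlap,
           same_type = e$sv_type == sv$sv_type)
  })
  bind_rows(rows)
}

#' Report expression-associated pharmacogene SVs
#'
#' One row per (gene, SV type) among eQTLs whose match passed the overlap
#' inclusion: coding/non-coding status from the annotation, affected TFBSs
#' for non-coding entries, tissue list, effect-size range and adjusted-p
#' range, and the count of same-type matched SVs. Unmatched eQTLs are
#' excluded and tallied in the log.
#'
#' @param matches Output of [match_eqtl()].
#' @param eqtls The eQTL table the matches refer to.
#' @param annotated An `annotated_sv` table (for coding status).
#' @param regulatory_hits Optional output of [coexpression_filter()] (TF
#'   lists for non-coding rows).
#' @return Tibble with columns `gene`, `sv_type`, `sv_function`, `tfbs`,
#'   `tissues`, `neglog10_bh_min`, `neglog10_bh_max`, `beta_min`, `beta_max`,
#'   `n_matched_svs`.
#' @export
eqtl_report <- function(matches, eqtls, annotated, regulatory_hits = NULL) {
  inc <- matches |> filter(.data$included)
  d <- inner_join(inc, eqtls, by = "eqtl_id")
  ann <- as_tibble(annotated)
  rep_tbl <- d |>
    group_by(.data$gene, .data$sv_type) |>
    summarise(
      sv_ids = list(unique(.data$sv_id)),
      tissues = paste(sort(unique(.data$tissue)), collapse = ","),
      neglog10_bh_min = min(.data$neglog10_bh),
      neglog10_bh_max = max(.data$neglog10_bh),
      beta_min = min(.data$beta), beta_max = max(.data$beta),
      n_matched_svs = sum(.data$same_type),
      .groups = "drop"
    )
  rep_tbl$sv_function <- vapply(seq_len(nrow(rep_tbl)), function(i) {
    rows <- ann[ann$sv_id %in% rep_tbl$sv_ids[[i]] &
                  ann$symbol == rep_tbl$gene[i], ]
    if (nrow(rows) == 0) "unassigned"
    else if (any(rows$coding)) "coding" else "non-coding"
  }, character(1))
  rep_tbl$tfbs <- vapply(seq_len(nrow(rep_tbl)), function(i) {
    if (rep_tbl$sv_function[i] != "non-coding" || is.null(regulatory_hits)) {
      return("")
    }
    tfs <- regulatory_hits$tf_name[
      regulatory_hits$sv_id %in% rep_tbl$sv_ids[[i]] &
        regulatory_hits$symbol == rep_tbl$gene[i]
    ]
    paste(sort(unique(tfs)), collapse = ",")
  }, character(1))
  out <- rep_tbl |>
    select("gene", "sv_type", "sv_function", "tfbs", "tissues",
           "neglog10_bh_min", "neglog10_bh_max", "beta_min", "beta_max",
           "n_matched_svs")
  out <- add_log(out, "eqtl", "eqtls_total", nrow(matches))
  out <- add_log(out, "eqtl", "eqtls_included", nrow(inc))
  add_log(out, "eqtl", "eqtls_excluded", nrow(matches) - nrow(inc))
}
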