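#' Read transcription-factor binding-site cluster peaks
#'
#' BED 5+ dialect: `chrom`, `start`, `end` (0-based half-open), `tf_name`,
#' `peak_score`, `studies` as `"k/N"` (studies observing the peak out of
#' studies total).
#'
#' @param path BED-like TSV, with or without a header line.
#' @return Tibble with columns `chrom`, `start`, `end`, `tf_name`,
#'   `peak_score`, `studies_observed`, `studies_total`.
#' @export
read_tfbs_bed <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  has_header <- grepl("chrom", first, fixed = TRUE)
  d <- readr::read_tsv(
    path, col_names = if (has_header) TRUE else
      c("chrom", "start", "end", "tf_name", "peak_score", "studies"),
    skip = 0, show_col_types = FALSE
  )
  st <- strsplit(as.character(d$studies), "/", fixed = TRUE)
  d$studies_observed <- as.integer(vapply(st, `[`, character(1), 1))
  d$studies_total <- as.integer(vapply(st, `[`, character(1), 2))
  d$studies <- NULL
  if (any(d$studies_observed > d$studies_total)) {
    abort("studies_observed exceeds studies_total")
  }
  as_tibble(d)
}

#' Filter TFBS peaks on score and study support
#'
#' Retains peaks with `peak_score >= min_score` (default 200) and support
#' from at least `min_studies` studies (default 2, excluding single-study
#' observations).
#'
#' @param peaks Tibble from [read_tfbs_bed()].
#' @param min_score Minimum peak score (inclusive).
#' @param min_studies Minimum number of observing studies (inclusive).
#' @return Filtered peak tibble.
#' @export
#' @examples
#' peaks <- tibble::tibble(chrom = "chr1", start = 0, end = 10,
#'                         tf_name = "CTCF", peak_score = c(199, 950, 200),
#'                         studies_observed = c(3, 1, 2),
#'                         studies_total = 1264)
#' filter_tfbs(peaks)
filter_tfbs <- function(peaks, min_score = 200L, min_studies = 2L) {
  out <- peaks[peaks$peak_score >= min_score &
                 peaks$studies_observed >= min_studies, ]
  out <- add_log(out, "tfbs_filter", "input", nrow(peaks))
  add_log(out, "tfbs_filter", "retained", nrow(out))
}

#' Overlap non-coding SVs with TFBS peaks
#'
#' Emits one deduplicated (SV, gene, TF) triple per non-coding SV whose
#' interval intersects a retained peak by at least 1 bp. By default the whole
#' SV interval is evaluated; `region = "gene_flank"` restricts the evaluated
#' window to the intersection of the SV with the gene span extended by
#' `flank` bp, for SVs that extend far beyond the gene they are assigned to.
#'
#' @param noncoding An `annotated_sv` table restricted to non-coding rows
#'   (rows with `coding == FALSE`; coding rows are dropped with a warning).
#' @param peaks Filtered TFBS peaks.
#' @param gene_set Required for `region = "gene_flank"`.
#' @param region `"sv"` (any overlap with the SV) or `"gene_flank"`.
#' @param flank Flank in bp for `region = "gene_flank"`.
#' @return Tibble with columns `sv_id`, `gene_id`, `symbol`, `tf_name`,
#'   `sv_type`, `af_used` plus per-population frequencies.
#' @export
overlap_tfbs <- function(noncoding, peaks, gene_set = NULL,
                         region = c("sv", "gene_flank"), flank = 10000L) {
  region <- match.arg(region)
  nc <- as_tibble(noncoding)
  if (any(nc$coding)) {
    warn("dropping coding rows from overlap_tfbs() input")
    nc <- nc[!nc$coding, ]
  }
  if (nrow(nc) == 0 || nrow(peaks) == 0) {
    return(tibble(sv_id = character(), gene_id = character(),
                  symbol = character(), tf_name = character()))
  }
  win <- nc
  if (region == "gene_flank") {
    if (is.null(gene_set)) abort("gene_set required for region = 'gene_flank'")
    g <- gene_set$genes[match(nc$gene_id, gene_set$genes$gene_id), ]
    win$start <- pmax(nc$start, g$start - flank)
    win$end <- pmin(nc$end, g$end + flank)
    keep <- win$start < win$end
    win <- win[keep, ]
    nc <- nc[keep, ]
  }
  hits <- GenomicRanges::findOverlaps(as_granges0(win), as_granges0(peaks))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  out <- tibble(
    sv_id = nc$sv_id[qi], gene_id = nc$gene_id[qi], symbol = nc$symbol[qi],
    tf_name = peaks$tf_name[si], sv_type = nc$sv_type[qi],
    component = nc$component[qi], af_used = nc$af_used[qi],
    af_afr = nc$af_afr[qi], af_amr = nc$af_amr[qi], af_eas = nc$af_eas[qi],
    af_eur = nc$af_eur[qi], af_oth = nc$af_oth[qi]
  ) |>
    distinct(.data$sv_id, .data$gene_id, .data$tf_name, .keep_all = TRUE)
  out
}

#' Read a gene/TF x tissue median expression matrix
#'
#' TSV with a `symbol` column followed by one column per tissue; values are
#' median expression (TPM-like, non-negative).
#'
#' @param path TSV path.
#' @return Numeric matrix with symbols as rownames.
#' @export
read_expression_matrix <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(d[, -1])
  rownames(m) <- d[[1]]
  if (any(m < 0)) abort("expression values must be non-negative")
  if (anyDuplicated(colnames(m))) abort("tissue names must be unique")
  m
}

#' Retain SV-TF pairs supported by tissue co-expression
#'
#' A pair is retained when the affected gene and the transcription factor are
#' both expressed (median expression >= `threshold`) in at least one tissue
#' of the panel; `tissues_supported` lists every such tissue. Pairs whose
#' gene or TF symbol is absent from the matrix are dropped and counted in
#' the log.
#'
#' @param pairs Output of [overlap_tfbs()] (needs `symbol` and `tf_name`).
#' @param expr Expression matrix from [read_expression_matrix()].
#' @param tissues Tissue panel (default [pgx_tissues()]); must be a subset of
#'   the matrix columns.
#' @param threshold Expression level above which a gene counts as expressed
#'   (median TPM >= 1 by default).
#' @return Tibble of regulatory hits with list-column `tissues_supported` and
#'   a `direction_hint` (`ablation` for DEL/MCNV-del, `gain` for
#'   DUP/MCNV-dup, `insertion-disruption` for INS, `complex` for CPX/INV).
#' @export
coexpression_filter <- function(pairs, expr, tissues = pgx_tissues(),
                                threshold = 1) {
  if (!all(tissues %in% colnames(expr))) {
    abort(paste0("tissue(s) missing from expression matrix: ",
                 paste(setdiff(tissues, colnames(expr)), collapse = ", ")))
  }
  present <- pairs$symbol %in% rownames(expr) & pairs$tf_name %in% rownames(expr)
  n_missing <- sum(!present)
  p <- pairs[present, ]
  if (nrow(p) == 0) {
    out <- p
    out$tissues_supported <- list()
    out$direction_hint <- character(0)
  } else {
    ex_gene <- expr[p$symbol, tissues, drop = FALSE] >= threshold
    ex_tf <- expr[p$tf_name, tissues, drop = FALSE] >= threshold
    both <- ex_gene & ex_tf
    supported <- apply(both, 1, function(r) tissues[r], simplify = FALSE)
    p$tissues_supported <- supported
    comp_type <- ifelse(p$sv_type == "MCNV", paste0("MCNV_", p$component),
                        p$sv_type)
    p$direction_hint <- dplyr::case_when(
      comp_type %in% c("DEL", "MCNV_DEL") ~ "ablation",
      comp_type %in% c("DUP", "MCNV_DUP") ~ "gain",
      comp_type == "INS" ~ "insertion-disruption",
      TRUE ~ "complex"
    )
    out <- p[lengths(supported) > 0, ]
  }
  out <- add_log(out, "coexpression", "input_pairs", nrow(pairs))
  out <- add_log(out, "coexpression", "missing_symbol", n_missing)
  add_log(out, "coexpression", "retained", nrow(out))
}
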