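#' Read a cohort structural-variant table
#'
#' Parses either the documented TSV dialect or a VCF 4.2 with SV INFO keys
#' into a normalized cohort SV table: 0-based half-open coordinates, one row
#' per SV, global and per-population allele frequencies, and the multiallelic
#' copy-number spectrum for MCNV records. Per-population frequencies that are
#' absent in the input stay `NA` (absent-marked, never silently zero).
#'
#' The TSV dialect has columns `sv_id`, `chrom`, `start`, `end`, `sv_type`,
#' `filter`, `length_bp`, `af`, optional `af_afr`, `af_amr`, `af_eas`,
#' `af_eur`, `af_oth`, optional `mcnv_spectrum` (e.g. `"0:0.05,2:0.80,3:0.15"`,
#' copy state : allele frequency), optional `singleton`.
#'
#' Insertions are stored as 1-bp intervals at the insertion point with
#' `length_bp` carrying the insert size, so interval overlap works uniformly
#' while size statistics stay correct.
#'
#' @param path Input file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param info_keys For VCF input, the INFO field names, as a named list with
#'   entries `end`, `svtype`, `svlen`, `af`, `pop_af` (named character vector
#'   population -> key) and `mcnv` (comma-separated copy-state frequencies
#'   starting at copy state 0).
#' @return A tibble of class `sv_table` with a provenance log
#'   (see [pgx_log()]).
#' @export
read_sv_table <- function(path, dialect = c("tsv", "vcf"),
                          info_keys = list(
                            end = "END", svtype = "SVTYPE", svlen = "SVLEN",
                            af = "AF",
                            pop_af = c(AFR = "AFR_AF", AMR = "AMR_AF",
                                       EAS = "EAS_AF", EUR = "EUR_AF",
                                       OTH = "OTH_AF"),
                            mcnv = "CN_FREQ")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    d <- readr::read_tsv(path, show_col_types = FALSE)
    need <- c("sv_id", "chrom", "start", "end", "sv_type", "filter", "af")
    if (!all(need %in% names(d))) {
      abort(paste0("SV TSV is missing column(s): ",
                   paste(setdiff(need, names(d)), collapse = ", ")))
    }
    for (p in tolower(pgx_populations())) {
      col <- paste0("af_", p)
      if (!col %in% names(d)) d[[col]] <- NA_real_
    }
    if (!"mcnv_spectrum" %in% names(d)) d$mcnv_spectrum <- NA_character_
    if (!"singleton" %in% names(d)) d$singleton <- FALSE
    if (!"length_bp" %in% names(d)) d$length_bp <- d$end - d$start
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    getinfo <- function(key, as = "character") {
      vcfR::extract.info(v, element = key, as.numeric = (as == "numeric"))
    }
    endv <- suppressWarnings(as.numeric(getinfo(info_keys$end)))
    svtype <- getinfo(info_keys$svtype)
    svlen <- suppressWarnings(abs(as.numeric(getinfo(info_keys$svlen))))
    af <- suppressWarnings(as.numeric(getinfo(info_keys$af)))
    pos <- as.numeric(fix$POS)
    d <- tibble(
      sv_id = fix$ID,
      chrom = fix$CHROM,
      start = pos - 1,             # VCF 1-based -> 0-based half-open
      end = ifelse(is.na(endv), pos - 1 + svlen, endv),
      sv_type = svtype,
      filter = fix$FILTER,
      length_bp = svlen,
      af = af,
      mcnv_spectrum = getinfo(info_keys$mcnv),
      singleton = FALSE
    )
    for (p in names(info_keys$pop_af)) {
      d[[paste0("af_", tolower(p))]] <-
        suppressWarnings(as.numeric(getinfo(info_keys$pop_af[[p]])))
    }
    # CN_FREQ: frequencies for copy states 0,1,2,... -> "state:freq" string
    d$mcnv_spectrum <- ifelse(
      is.na(d$mcnv_spectrum), NA_character_,
      vapply(strsplit(d$mcnv_spectrum, ","), function(fr) {
        fr <- as.numeric(fr)
        paste(paste0(seq_along(fr) - 1L, ":", fr), collapse = ",")
      }, character(1))
    )
  }
  d <- normalize_sv_records(d)
  new_sv_table(d, source = path)
}

normalize_sv_records <- function(d) {
  d$sv_type <- toupper(d$sv_type)
  d$sv_type[d$sv_type %in% c("BND", "UNR")] <- "BND_UNRESOLVED"
  d$type_known <- d$sv_type %in% sv_types()
  # INS normalized to 1-bp point interval; keep reported insert size
  is_ins <- d$sv_type == "INS"
  d$length_bp <- ifelse(is_ins & !is.na(d$length_bp), d$length_bp,
                        d$end - d$start)
  d$end <- ifelse(is_ins, d$start + 1, d$end)
  if (any(d$length_bp < 0, na.rm = TRUE)) abort("negative SV length")
  afc <- c("af", paste0("af_", tolower(pgx_populations())))
  for (col in afc) {
    bad <- !is.na(d[[col]]) & (d[[col]] < 0 | d[[col]] > 1)
    if (any(bad)) abort(paste0("allele frequency outside [0,1] in ", col))
  }
  mc <- !is.na(d$mcnv_spectrum)
  if (any(mc & d$sv_type != "MCNV")) {
    abort("mcnv_spectrum present on a non-MCNV record")
  }
  d$start <- as.integer(d$start); d$end <- as.integer(d$end)
  d
}

new_sv_table <- function(d, source = NA_character_) {
  if (anyDuplicated(d$sv_id)) abort("duplicate sv_id in SV table")
  out <- as_tibble(d)
  class(out) <- c("sv_table", class(out))
  attr(out, "source") <- source
  add_log(out, "ingest", "input", nrow(out))
}

#' Apply record-level SV filters
#'
#' Retains records whose filter status is `PASS` or `MULTIALLELIC` and whose
#' type is neither an unresolved non-reference breakpoint junction nor a
#' reciprocal translocation. Records of unrecognized type are removed too.
#' Removal reasons are tallied in the provenance log; filtering is
#' idempotent.
#'
#' @param table An `sv_table`.
#' @return Filtered `sv_table` with an extended provenance log.
#' @export
filter_sv_records <- function(table) {
  ok_filter <- table$filter %in% c("PASS", "MULTIALLELIC")
  bad_type <- table$sv_type %in% c("BND_UNRESOLVED", "CTX")
  unknown <- !table$type_known
  keep <- ok_filter & !bad_type & !unknown
  out <- table[keep, ]
  class(out) <- class(table)
  attr(out, "source") <- attr(table, "source")
  attr(out, "pgx_log") <- pgx_log(table)
  out <- add_log(out, "filter", "non_pass_filter", sum(!ok_filter))
  out <- add_log(out, "filter", "excluded_type", sum(ok_filter & bad_type))
  out <- add_log(out, "filter", "unknown_type",
                 sum(ok_filter & !bad_type & unknown))
  out <- add_log(out, "filter", "retained", nrow(out))
  out
}

#' Parse an MCNV copy-state spectrum string
#'
#' @param x String like `"0:0.845,2:0.155"` (copy state : allele frequency).
#' @return Named numeric vector, names = copy states.
#' @export
parse_mcnv_spectrum <- function(x) {
  if (is.na(x) || !nzchar(x)) abort("MCNV spectrum missing")
  parts <- strsplit(strsplit(x, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  states <- vapply(parts, `[`, character(1), 1)
  freqs <- as.numeric(vapply(parts, `[`, character(1), 2))
  if (any(is.na(freqs)) || any(freqs < 0) || sum(freqs) > 1 + 1e-9) {
    abort("invalid MCNV spectrum")
  }
  setNames(freqs, states)
}

#' Decompose a multiallelic CNV into deletion-like and duplication-like parts
#'
#' Copy states below the expected (reference) copy number contribute to the
#' deletion-like allele frequency, states above it to the duplication-like
#' frequency; the reference state contributes to neither. A single MCNV locus
#' can therefore appear as separate DEL-frequency and DUP-frequency entries,
#' e.g. a spectrum `{0: 0.845, 2: 0.155}` is a pure deletion at 84.5%.
#'
#' @param spectrum Named numeric vector (see [parse_mcnv_spectrum()]) or the
#'   spectrum string itself.
#' @param expected_cn Reference copy number (default 2, diploid).
#' @return List with elements `del_like_af` and `dup_like_af`.
#' @export
#' @examples
#' decompose_mcnv(c(`0` = 0.845, `2` = 0.155))
decompose_mcnv <- function(spectrum, expected_cn = 2) {
  if (is.character(spectrum) && length(spectrum) == 1) {
    spectrum <- parse_mcnv_spectrum(spectrum)
  }
  if (is.null(names(spectrum))) abort("spectrum must be named by copy state")
  cn <- as.numeric(names(spectrum))
  list(del_like_af = sum(spectrum[cn < expected_cn]),
       dup_like_af = sum(spectrum[cn > expected_cn]))
}

#' Write a normalized SV TSV
#'
#' @param table An `sv_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sv_table <- function(table, path) {
  readr::write_tsv(as_tibble(table), path)
  invisible(path)
}
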