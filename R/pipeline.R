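#' Build and validate a pipeline configuration
#'
#' @param gene_annotation,panel,sv_table,tfbs,expression,eqtl Input paths
#'   (eQTL optional).
#' @param sv_dialect `"tsv"` or `"vcf"`.
#' @param tissues Tissue panel for the co-expression filter.
#' @param min_score,min_studies TFBS filter thresholds.
#' @param expr_threshold Expression level counted as "expressed".
#' @param maf_common Common/rare frequency boundary.
#' @param near_bp,min_overlap eQTL matching thresholds.
#' @param n_individuals Simulated cohort size.
#' @param n_snv_adme,n_snv_targets Literature per-individual functional SNV
#'   burdens used by the attribution.
#' @param seed RNG seed for the cohort simulation.
#' @return A validated list of class `pgx_config`.
#' @export
pgx_config <- function(gene_annotation, panel, sv_table, tfbs, expression,
                       eqtl = NULL, sv_dialect = "tsv",
                       tissues = pgx_tissues(),
                       min_score = 200L, min_studies = 2L,
                       expr_threshold = 1, maf_common = 0.01,
                       near_bp = 100L, min_overlap = 0.99,
                       n_individuals = 100000L,
                       n_snv_adme = 40.6, n_snv_targets = 26, seed = 1L) {
  cfg <- as.list(environment())
  if (length(cfg$tissues) == 0) abort("tissue panel must not be empty")
  if (cfg$min_overlap < 0 || cfg$min_overlap > 1) {
    abort("min_overlap must lie in [0, 1]")
  }
  if (cfg$maf_common <= 0 || cfg$maf_common >= 1) {
    abort("maf_common must lie in (0, 1)")
  }
  if (cfg$n_individuals <= 0) abort("n_individuals must be positive")
  for (p in c("gene_annotation", "panel", "sv_table", "tfbs", "expression")) {
    if (!file.exists(cfg[[p]])) abort(paste0("input not readable: ", cfg[[p]]))
  }
  structure(cfg, class = "pgx_config")
}

#' Run the full pharmacogenomic SV pipeline
#'
#' ingest -> filter -> cluster -> gene assignment and functional
#' classification -> TFBS/co-expression screen of non-coding SVs -> burdens
#' and carrier simulation -> eQTL cross-reference -> attribution of
#' non-coding variability. Every stage logs its input/output record counts;
#' a failing stage aborts with the stage name and the partial outputs
#' produced so far attached as a condition field.
#'
#' @param config A [pgx_config()].
#' @return List of class `pgx_run` with elements `annotated`, `density`,
#'   `regulatory_hits`, `burden`, `cohort_sim`, `eqtl_matches`,
#'   `eqtl_report`, `attribution`, `summary` and `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pgx_config"))
  outputs <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            partial_outputs = names(outputs))
    })
  }

  gs <- stage("genome_model",
              read_gene_models(config$gene_annotation, config$panel))
  raw <- stage("ingest", read_sv_table(config$sv_table,
                                       dialect = config$sv_dialect))
  kept <- stage("filter", filter_sv_records(raw))
  clustered <- stage("cluster", cluster_sv_table(kept))
  annotated <- stage("annotate", annotate_svs(clustered, gs))
  outputs$annotated <- annotated
  outputs$density <- stage("density", density_table(annotated, gs))

  noncoding <- annotated |> filter(!.data$coding)
  peaks <- stage("tfbs", filter_tfbs(read_tfbs_bed(config$tfbs),
                                     min_score = config$min_score,
                                     min_studies = config$min_studies))
  pairs <- stage("tfbs_overlap", overlap_tfbs(noncoding, peaks))
  expr <- stage("expression", read_expression_matrix(config$expression))
  hits <- stage("coexpression",
                coexpression_filter(pairs, expr, tissues = config$tissues,
                                    threshold = config$expr_threshold))
  outputs$regulatory_hits <- hits

  outputs$burden <- stage("burden", expected_burden(annotated))
  func <- annotated |>
    filter(.data$functional_class %in% c("LOF", "IGD"), !is.na(.data$af_used)) |>
    distinct(.data$sv_id, .keep_all = TRUE)
  outputs$cohort_sim <- stage("simulate",
                              simulate_cohort(func, n = config$n_individuals,
                                              seed = config$seed))

  if (!is.null(config$eqtl)) {
    eqtls <- stage("eqtl_read", read_eqtl_table(config$eqtl))
    outputs$eqtl_matches <- stage("eqtl_match",
                                  match_eqtl(eqtls, clustered,
                                             near_bp = config$near_bp,
                                             min_overlap = config$min_overlap))
    outputs$eqtl_report <- stage("eqtl_report",
                                 eqtl_report(outputs$eqtl_matches, eqtls,
                                             annotated, hits))
  }

  # non-coding functional burden: dosage over distinct regulatory-hit SVs
  nc_sv <- hits |> distinct(.data$sv_id, .data$gene_id, .keep_all = TRUE)
  n_ncsv <- sum(2 * nc_sv$af_used, na.rm = TRUE)
  coding_burden <- combine_burden(outputs$burden)
  n_csv <- sum(coding_burden$burden_total[coding_burden$group %in%
                                            c("ADME", "drug_target")])
  outputs$attribution <- stage(
    "attribution",
    attribution_summary(n_ncsv, n_csv,
                        n_snv = config$n_snv_adme + config$n_snv_targets)
  )

  outputs$summary <- counts_summary(annotated, hits)
  outputs$log <- bind_rows(
    pgx_log(annotated) |> mutate(table = "annotated"),
    pgx_log(peaks) |> mutate(table = "tfbs"),
    pgx_log(hits) |> mutate(table = "regulatory")
  )
  structure(outputs, class = "pgx_run")
}

#' Coding/non-coding partition with headline percentages
#'
#' Bookkeeping over precomputed marginals: given the total number of
#' pharmacogenomic SVs and the number affecting exons, reports the
#' non-coding count, the coding share (one decimal and headline integer
#' percent), and optionally the TFBS-overlap share among non-coding SVs.
#'
#' @param n_total Total SV count.
#' @param n_coding SVs impacting at least one exon.
#' @param n_tfbs Optional count of non-coding SVs overlapping a TFBS.
#' @return One-row tibble with `n_total`, `n_coding`, `n_noncoding`,
#'   `coding_pct`, `coding_pct_headline`, and when `n_tfbs` is given
#'   `tfbs_pct` (one decimal, share of non-coding SVs).
#' @export
#' @examples
#' partition_summary(14984, 2198, n_tfbs = 2958)
partition_summary <- function(n_total, n_coding, n_tfbs = NULL) {
  stopifnot(n_coding <= n_total)
  out <- tibble(
    n_total = n_total, n_coding = n_coding,
    n_noncoding = n_total - n_coding,
    coding_pct = percent_of(n_coding / n_total),
    coding_pct_headline = percent_of(n_coding / n_total, headline = TRUE)
  )
  if (!is.null(n_tfbs)) {
    out$n_tfbs <- n_tfbs
    out$tfbs_pct <- percent_of(n_tfbs / out$n_noncoding)
  }
  out
}

#' Summarize an annotated SV table
#'
#' Totals, coding/non-coding split with percentages, functional-class and
#' rarity breakdowns per gene group, and per-type size medians.
#'
#' @param annotated An `annotated_sv` table.
#' @param regulatory_hits Optional co-expression-filtered hits, adding the
#'   TFBS-overlap share of non-coding SVs.
#' @return List with `partition`, `by_class`, `rarity`, `sizes`.
#' @export
counts_summary <- function(annotated, regulatory_hits = NULL) {
  d <- as_tibble(annotated)
  sv_level <- d |>
    group_by(.data$sv_id) |>
    summarise(coding = any(.data$coding),
              sv_type = first(.data$sv_type),
              size_bp = first(.data$size_bp), .groups = "drop")
  n_tfbs <- if (!is.null(regulatory_hits)) {
    length(unique(regulatory_hits$sv_id))
  } else NULL
  partition <- partition_summary(nrow(sv_level), sum(sv_level$coding),
                                 n_tfbs = n_tfbs)
  by_class <- d |>
    count(.data$group, .data$panel_class, .data$functional_class)
  rarity <- d |>
    count(.data$group, .data$panel_class, .data$rarity) |>
    group_by(.data$group, .data$panel_class) |>
    mutate(pct = percent_of(.data$n / sum(.data$n))) |>
    ungroup()
  sizes <- sv_level |>
    group_by(.data$sv_type) |>
    summarise(n = n(), median_bp = stats::median(.data$size_bp),
              .groups = "drop")
  list(partition = partition, by_class = by_class, rarity = rarity,
       sizes = sizes)
}

#' @export
print.pgx_run <- function(x, ...) {
  cat("<pgx_run>\n")
  print(x$summary$partition)
  cat("attribution:\n")
  print(x$attribution)
  invisible(x)
}
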