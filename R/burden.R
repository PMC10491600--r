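#' Expected per-individual SV burden
#'
#' The burden of a set of functional SVs is the expected diploid allele
#' dosage, `sum(2 * AF)` over SVs, grouped by gene group and functional
#' class. MCNV loci contribute through their decomposed deletion-like and
#' duplication-like component frequencies. Multi-gene SVs contribute once per
#' gene (each gene's burden is interpretable on its own). A carrier-based
#' alternative, `sum(1 - (1 - AF)^2)`, is available via `metric`.
#'
#' @param annotated An `annotated_sv` table.
#' @param population `"global"` or one of [pgx_populations()]. For a specific
#'   population, SVs lacking that population's frequency are skipped and
#'   counted in the log.
#' @param include_classes Functional classes that count as functional
#'   (default LOF and IGD).
#' @param metric `"dosage"` (default) or `"carrier"`.
#' @return List of class `burden_report`: `by_group` (population, group,
#'   functional_class, burden, n_sv), `contributions` (per SV x gene row),
#'   `skipped` (count of rows without the requested frequency).
#' @export
#' @examples
#' # one LOF SV at AF 0.5 contributes an expected dosage of 1.0
expected_burden <- function(annotated, population = "global",
                            include_classes = c("LOF", "IGD"),
                            metric = c("dosage", "carrier")) {
  metric <- match.arg(metric)
  stopifnot(population %in% c("global", pgx_populations()))
  d <- annotated |>
    as_tibble() |>
    filter(.data$functional_class %in% include_classes)
  af_col <- if (population == "global") "af_used"
            else paste0("af_", tolower(population))
  af <- d[[af_col]]
  skipped <- sum(is.na(af))
  d <- d[!is.na(af), ]
  af <- af[!is.na(af)]
  d$contribution <- if (metric == "dosage") 2 * af else 1 - (1 - af)^2
  d$population <- population
  by_group <- d |>
    group_by(.data$population, .data$group, .data$functional_class) |>
    summarise(burden = sum(.data$contribution), n_sv = n(), .groups = "drop")
  structure(
    list(by_group = by_group,
         contributions = select(d, "population", "sv_id", "gene_id", "group",
                                "functional_class", "contribution"),
         skipped = skipped,
         metric = metric),
    class = "burden_report"
  )
}

#' @export
print.burden_report <- function(x, ...) {
  cat("<burden_report> metric =", x$metric,
      "| skipped (no frequency):", x$skipped, "\n")
  print(x$by_group)
  invisible(x)
}

#' Combine burden components into per-group coding totals
#'
#' Sums the functional classes within each gene group, e.g. LOF + IGD
#' components of 7.9 + 2.4 combine to a coding burden of 10.3.
#'
#' @param report A `burden_report`.
#' @return Tibble with `population`, `group`, `burden_total`.
#' @export
combine_burden <- function(report) {
  report$by_group |>
    group_by(.data$population, .data$group) |>
    summarise(burden_total = sum(.data$burden), .groups = "drop")
}

#' Simulate a diploid cohort under Hardy-Weinberg equilibrium
#'
#' For each SV, `n` individuals draw two alleles at the reported allele
#' frequency (loci independent, no linkage); genotype counts are multinomial
#' with probabilities `((1-p)^2, 2p(1-p), p^2)`. Carriers hold at least one
#' alternate allele.
#'
#' @param svs Tibble with columns `sv_id` and `af` (or `af_used`).
#' @param n Number of simulated individuals (default 100,000).
#' @param seed RNG seed (default 1).
#' @return Tibble of class `simulated_cohort` with per-SV columns `carriers`,
#'   `homozygotes`, `carrier_fraction`, `hom_fraction`, `mean_dosage`
#'   (alternate alleles per individual); attributes `n` and `seed`.
#' @export
simulate_cohort <- function(svs, n = 100000L, seed = 1L) {
  if (n <= 0) abort("n must be positive")
  af <- if ("af" %in% names(svs)) svs[["af"]] else svs[["af_used"]]
  if (is.null(af)) abort("svs must carry an `af` or `af_used` column")
  if (any(is.na(af)) || any(af < 0 | af > 1)) {
    abort("allele frequencies must be in [0,1]")
  }
  set.seed(seed)
  counts <- vapply(af, function(p) {
    drop(rmultinom(1, n, c((1 - p)^2, 2 * p * (1 - p), p^2)))
  }, numeric(3))
  het <- counts[2, ]; hom <- counts[3, ]
  out <- tibble(
    sv_id = svs$sv_id, af = af,
    carriers = het + hom, homozygotes = hom,
    carrier_fraction = (het + hom) / n, hom_fraction = hom / n,
    mean_dosage = (het + 2 * hom) / n
  )
  class(out) <- c("simulated_cohort", class(out))
  attr(out, "n") <- as.integer(n)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Express a carrier fraction as "1 in N individuals"
#'
#' `N = round(1 / fraction)`; fractions of 0.75 and above are reported as
#' `"1 per individual"`, a fraction of zero as `"0"`.
#'
#' @param fraction Carrier fraction(s) in `[0, 1]`.
#' @return Character vector.
#' @export
#' @examples
#' carrier_ratio(c(0.105, 0.4509, 1))
carrier_ratio <- function(fraction) {
  stopifnot(all(fraction >= 0 & fraction <= 1))
  out <- character(length(fraction))
  out[fraction == 0] <- "0"
  out[fraction >= 0.75] <- "1 per individual"
  mid <- fraction > 0 & fraction < 0.75
  out[mid] <- paste0("1 in ", round(1 / fraction[mid]))
  out
}
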