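#' Share of pharmacogenomic variability attributable to non-coding SVs
#'
#' The attributable fraction is
#' \deqn{f = \frac{n_{ncSV}}{n_{ncSV} + n_{SNV} + n_{cSV}}}
#' where `n_ncsv` is the number of putatively functional non-coding SVs per
#' individual, `n_csv` the number of functional exonic SVs per individual
#' (ADME genes plus drug targets), and `n_snv` the number of functional SNVs
#' per individual. The SNV count is an externally supplied constant taken
#' from the literature (defaults: 40.6 for ADME genes + 26 for drug targets),
#' never computed here.
#'
#' @param n_ncsv Functional non-coding SVs per individual.
#' @param n_csv Functional exonic SVs per individual.
#' @param n_snv Functional SNVs per individual
#'   (default `n_snv_adme + n_snv_targets`).
#' @param n_snv_adme,n_snv_targets Literature SNV burdens used when `n_snv`
#'   is not given.
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' # per-individual components: 21.7 non-coding SVs, 10.3 + 1.5 coding SVs
#' attribute_variability(21.7, 10.3 + 1.5)  # ~0.217, i.e. about 22%
attribute_variability <- function(n_ncsv, n_csv,
                                  n_snv = n_snv_adme + n_snv_targets,
                                  n_snv_adme = 40.6, n_snv_targets = 26) {
  if (any(c(n_ncsv, n_csv, n_snv) < 0)) abort("components must be >= 0")
  denom <- n_ncsv + n_snv + n_csv
  if (denom == 0) abort("all components are zero; the fraction is undefined")
  n_ncsv / denom
}

#' Format an attribution summary
#'
#' @param n_ncsv,n_csv,n_snv Components as in [attribute_variability()].
#' @return A one-row tibble with the components and the fraction as a percent
#'   with one decimal.
#' @export
attribution_summary <- function(n_ncsv, n_csv, n_snv = 40.6 + 26) {
  f <- attribute_variability(n_ncsv, n_csv, n_snv)
  tibble(n_ncsv = n_ncsv, n_csv = n_csv, n_snv = n_snv,
         fraction = f, percent = percent_of(f),
         percent_headline = percent_of(f, headline = TRUE))
}
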