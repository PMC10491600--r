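#' Merge overlapping and directly adjacent intervals
#'
#' Single-chromosome interval clustering with `max_dist = 0` merging
#' overlapping and bookended intervals (in half-open coordinates, "directly
#' adjacent" means `end1 == start2`). Output clusters are pairwise separated
#' by more than `max_dist`; every input id lands in exactly one cluster; the
#' result is invariant to input order (records are sorted internally by
#' start, end, then id).
#'
#' @param records Tibble with columns `chrom`, `start`, `end`, `id`
#'   (0-based half-open).
#' @param max_dist Maximum gap (bp) across which intervals are still merged.
#' @return Tibble with columns `cluster_id`, `chrom`, `start`, `end`,
#'   `n_members` and a list-column `member_ids`.
#' @export
#' @examples
#' cluster_intervals(tibble::tibble(chrom = "chr1",
#'                                  start = c(100, 200), end = c(200, 300),
#'                                  id = c("a", "b")))
cluster_intervals <- function(records, max_dist = 0L) {
  if (nrow(records) == 0) {
    return(tibble(cluster_id = integer(), chrom = character(),
                  start = integer(), end = integer(), n_members = integer(),
                  member_ids = list()))
  }
  if (length(unique(records$chrom)) > 1) {
    abort("cluster_intervals() expects records on one chromosome")
  }
  if (max_dist < 0) abort("max_dist must be >= 0")
  records <- arrange(records, .data$start, .data$end, .data$id)
  ir <- IRanges::IRanges(records$start + 1L, records$end)
  red <- IRanges::reduce(ir, min.gapwidth = max_dist + 1L, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  tibble(
    cluster_id = seq_along(red),
    chrom = records$chrom[1],
    start = BiocGenerics::start(red) - 1L,
    end = BiocGenerics::end(red),
    n_members = lengths(revmap),
    member_ids = lapply(revmap, function(i) records$id[i])
  )
}

#' Aggregate an SV table into non-redundant SVs
#'
#' Clusters records genome-wide within each (chromosome, SV type) stratum —
#' the cohort-table order of operations: merge first, then restrict to the
#' gene panel. Each cluster becomes one representative SV: the merged
#' interval, the member list, and a representative frequency (the maximum
#' member frequency by default, which avoids double-counting overlapping
#' call fragments; `freq = "sum"` adds them). Per-population frequencies and
#' the MCNV spectrum are taken from the member with the highest global
#' frequency. Insertions cluster by insertion point (1-bp intervals).
#'
#' @param svs An `sv_table` (after [filter_sv_records()]).
#' @param max_dist Merge gap passed to [cluster_intervals()].
#' @param freq `"max"` or `"sum"` member frequencies.
#' @return An `sv_table` of clustered SVs with `members` list-column.
#' @export
cluster_sv_table <- function(svs, max_dist = 0L, freq = c("max", "sum")) {
  freq <- match.arg(freq)
  strata <- svs |>
    as_tibble() |>
    group_by(.data$chrom, .data$sv_type) |>
    group_split()
  out <- lapply(strata, function(d) {
    cl <- cluster_intervals(
      tibble(chrom = d$chrom, start = d$start, end = d$end, id = d$sv_id),
      max_dist = max_dist
    )
    rows <- lapply(seq_len(nrow(cl)), function(i) {
      m <- d[match(cl$member_ids[[i]], d$sv_id), ]
      rep_i <- which.max(replace(m$af, is.na(m$af), -1))
      rep_af <- function(x) {
        if (all(is.na(x))) NA_real_
        else if (freq == "max") max(x, na.rm = TRUE) else sum(x, na.rm = TRUE)
      }
      tibble(
        # singleton clusters keep the member id; merged ones get a locus id
        sv_id = if (cl$n_members[i] == 1) m$sv_id[1] else
          paste0(m$chrom[1], ":", cl$start[i], "-", cl$end[i], ":",
                 m$sv_type[1]),
        chrom = m$chrom[1], start = cl$start[i], end = cl$end[i],
        sv_type = m$sv_type[1], filter = m$filter[rep_i],
        length_bp = if (m$sv_type[1] == "INS") max(m$length_bp)
                    else cl$end[i] - cl$start[i],
        af = rep_af(m$af),
        af_afr = rep_af(m$af_afr), af_amr = rep_af(m$af_amr),
        af_eas = rep_af(m$af_eas), af_eur = rep_af(m$af_eur),
        af_oth = rep_af(m$af_oth),
        mcnv_spectrum = m$mcnv_spectrum[rep_i],
        singleton = all(m$singleton),
        type_known = TRUE,
        n_members = cl$n_members[i],
        members = list(cl$member_ids[[i]])
      )
    })
    bind_rows(rows)
  })
  out <- bind_rows(out) |> arrange(.data$chrom, .data$start, .data$end)
  res <- new_sv_table(out, source = attr(svs, "source"))
  attr(res, "pgx_log") <- pgx_log(svs)
  res <- add_log(res, "cluster", "input", nrow(svs))
  add_log(res, "cluster", "clusters", nrow(res))
}
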