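#' Common/rare classification of an SV frequency
#'
#' Common iff the reported SV allele frequency is >= 1%. The reported
#' alternate-allele frequency is used directly (not folded), so an 84.5%
#' deletion is "common".
#'
#' @param af Allele frequency in `[0, 1]`.
#' @return Character vector, `"common"` or `"rare"`.
#' @export
#' @examples
#' rarity_class(c(0.010, 0.0099, 0.845))
rarity_class <- function(af) {
  stopifnot(all(af >= 0 & af <= 1, na.rm = TRUE))
  ifelse(af >= 0.01, "common", "rare")
}

#' Coding status of an SV relative to one gene
#'
#' An SV is coding when its interval intersects at least one exon of the
#' gene; insertions count when the insertion point lies inside an exon
#' (insertions are stored as 1-bp intervals, so plain intersection applies).
#'
#' @param start,end SV interval (0-based half-open).
#' @param gene_exons Tibble of the gene's exons (`start`, `end`).
#' @return Logical flag.
#' @export
set_coding_status <- function(start, end, gene_exons) {
  any(overlap_bp(start, end, gene_exons$start, gene_exons$end) > 0)
}

# functional consequence of one SV x gene pair; sv_type here is already a
# simple type (MCNV components arrive as DEL or DUP)
classify_one <- function(sv_type, start, end, gene, gene_exons, gene_cds) {
  coding <- set_coding_status(start, end, gene_exons)
  if (!coding) return(list(coding = FALSE, functional_class = "NONE"))
  # UTR-only hits are unclassifiable when CDS annotation distinguishes them
  frame_exons <- gene_exons
  if (!is.null(gene_cds)) {
    if (nrow(gene_cds) == 0 ||
        !any(overlap_bp(start, end, gene_cds$start, gene_cds$end) > 0)) {
      return(list(coding = TRUE, functional_class = "UNKNOWN"))
    }
    frame_exons <- gene_cds
  }
  contains_span <- start <= gene$start && end >= gene$end
  cls <- switch(
    sv_type,
    DEL = "LOF",
    INS = "LOF",
    INV = {
      bp_inside <- (start > gene$start && start < gene$end) ||
        (end > gene$start && end < gene$end)
      # whole-gene inversion with both breakpoints outside preserves the
      # transcription unit
      if (bp_inside) "LOF" else "UNKNOWN"
    },
    DUP = {
      if (contains_span) "IGD" else {
        affected <- sum(overlap_bp(start, end, frame_exons$start,
                                   frame_exons$end))
        if (affected %% 3 != 0) "LOF" else "UNKNOWN"
      }
    },
    CPX = "UNKNOWN",
    abort(paste0("unknown SV type '", sv_type, "'"))
  )
  list(coding = TRUE, functional_class = cls)
}

#' Classify the functional consequence of an SV on a gene
#'
#' Rule set: exon-intersecting deletions, exonic insertions, and inversions
#' with a breakpoint inside the gene span that cover at least one exon are
#' loss of function (LOF); duplications containing the whole gene span are
#' increased gene dosage (IGD); partial duplications hitting coding exons are
#' LOF when the summed affected coding bases are not a multiple of 3
#' (frameshift under tandem in-place duplication), otherwise UNKNOWN; complex
#' rearrangements over exons are UNKNOWN; non-coding SVs are NONE. With CDS
#' annotation present, exonic hits confined to UTRs are UNKNOWN.
#'
#' @param sv_type One of `DEL`, `DUP`, `INS`, `INV`, `CPX`.
#' @param start,end SV interval, 0-based half-open.
#' @param gene One row of `gene_set$genes`.
#' @param gene_exons,gene_cds Exon (and optional CDS) tibbles for that gene.
#' @return `"LOF"`, `"IGD"`, `"UNKNOWN"` or `"NONE"`.
#' @export
classify_function <- function(sv_type, start, end, gene, gene_exons,
                              gene_cds = NULL) {
  classify_one(sv_type, start, end, gene, gene_exons, gene_cds)$functional_class
}

#' Assign SVs to genes and annotate functional consequences
#'
#' Joins each SV to every gene whose span it intersects (multi-gene SVs are
#' counted once per gene), sets the coding flag, classifies the consequence,
#' and attaches rarity and size. MCNV records are decomposed into
#' deletion-like and duplication-like components
#' (see [decompose_mcnv()]); each component with non-zero allele frequency
#' yields its own row (`component` = `"DEL"`/`"DUP"`), classified under the
#' corresponding DEL/DUP rules, with population frequencies split
#' proportionally to the component share. MCNVs with no variant allele are
#' dropped and counted in the log.
#'
#' @param svs An `sv_table` (typically clustered).
#' @param gene_set A [new_gene_set()].
#' @param use_cds Honor CDS annotation for UTR-aware classification when the
#'   gene set carries it.
#' @return Tibble of class `annotated_sv`: one row per SV x gene
#'   (x MCNV component), columns `sv_id`, `gene_id`, `symbol`, `panel_class`,
#'   `group`, `chrom`, `start`, `end`, `sv_type`, `component`, `af_used`,
#'   per-population frequencies, `coding`, `functional_class`, `rarity`,
#'   `size_bp`.
#' @export
annotate_svs <- function(svs, gene_set, use_cds = TRUE) {
  d <- as_tibble(svs)
  gr_sv <- as_granges0(d)
  hits <- GenomicRanges::findOverlaps(gr_sv, gene_set$gr_span)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  exon_by_gene <- split(gene_set$exons, gene_set$exons$gene_id)
  cds_by_gene <- if (use_cds && !is.null(gene_set$cds)) {
    split(gene_set$cds, gene_set$cds$gene_id)
  } else NULL

  rows <- vector("list", length(qi))
  n_ref_mcnv <- 0L
  for (k in seq_along(qi)) {
    sv <- d[qi[k], ]
    gene <- gene_set$genes[si[k], ]
    gx <- exon_by_gene[[gene$gene_id]]
    gc <- if (!is.null(cds_by_gene)) {
      cds_by_gene[[gene$gene_id]] %||% gx[0, ]
    } else NULL

    if (sv$sv_type == "MCNV") {
      comp <- decompose_mcnv(sv$mcnv_spectrum)
      total <- comp$del_like_af + comp$dup_like_af
      if (total == 0) { n_ref_mcnv <- n_ref_mcnv + 1L; next }
      parts <- list()
      for (side in c("DEL", "DUP")) {
        caf <- if (side == "DEL") comp$del_like_af else comp$dup_like_af
        if (caf == 0) next
        cl <- classify_one(side, sv$start, sv$end, gene, gx, gc)
        share <- caf / total
        parts[[side]] <- tibble(
          sv_id = sv$sv_id, gene_id = gene$gene_id, symbol = gene$symbol,
          panel_class = gene$panel_class, group = gene$group,
          chrom = sv$chrom, start = sv$start, end = sv$end,
          sv_type = "MCNV", component = side, af_used = caf,
          af_afr = sv$af_afr * share, af_amr = sv$af_amr * share,
          af_eas = sv$af_eas * share, af_eur = sv$af_eur * share,
          af_oth = sv$af_oth * share,
          coding = cl$coding, functional_class = cl$functional_class,
          rarity = rarity_class(caf), size_bp = sv$length_bp
        )
      }
      rows[[k]] <- bind_rows(parts)
    } else {
      cl <- classify_one(sv$sv_type, sv$start, sv$end, gene, gx, gc)
      rows[[k]] <- tibble(
        sv_id = sv$sv_id, gene_id = gene$gene_id, symbol = gene$symbol,
        panel_class = gene$panel_class, group = gene$group,
        chrom = sv$chrom, start = sv$start, end = sv$end,
        sv_type = sv$sv_type, component = NA_character_, af_used = sv$af,
        af_afr = sv$af_afr, af_amr = sv$af_amr, af_eas = sv$af_eas,
        af_eur = sv$af_eur, af_oth = sv$af_oth,
        coding = cl$coding, functional_class = cl$functional_class,
        rarity = rarity_class(sv$af), size_bp = sv$length_bp
      )
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("annotated_sv", class(out))
  attr(out, "pgx_log") <- pgx_log(svs)
  out <- add_log(out, "annotate", "sv_gene_pairs", nrow(out))
  out <- add_log(out, "annotate", "reference_only_mcnv", n_ref_mcnv)
  out <- add_log(out, "annotate",
                 "svs_in_panel", length(unique(out$sv_id)))
  out
}

#' Per-gene SV density and class comparisons
#'
#' Counts distinct SVs per gene (SVs spanning several genes count once per
#' gene, including genes with zero SVs), normalizes by gene length in kb, and
#' runs two-sided Wilcoxon rank-sum comparisons of SVs/kb between requested
#' gene classes or groups. Raw p-values are reported; Benjamini-Hochberg
#' adjustment is available but off by default, matching the convention of
#' reporting raw two-sided p at alpha = 0.05.
#'
#' @param annotated An `annotated_sv` table.
#' @param gene_set The `gene_set` the annotation used.
#' @param comparisons List of 2-vectors of class (or group) labels to compare.
#' @param by `"group"` (ADME vs drug target vs olfactory) or `"class"`
#'   (panel families).
#' @param adjust Apply BH adjustment across the comparisons.
#' @return List with `per_gene` (gene_id, n_sv, gene_length_kb, svs_per_kb,
#'   class columns) and `comparisons` (class_a, class_b, n_a, n_b, statistic,
#'   p_value).
#' @export
density_table <- function(annotated, gene_set,
                          comparisons = list(c("ADME", "drug_target")),
                          by = c("group", "class"), adjust = FALSE) {
  by <- match.arg(by)
  counts <- annotated |>
    as_tibble() |>
    distinct(.data$gene_id, .data$sv_id) |>
    count(.data$gene_id, name = "n_sv")
  per_gene <- gene_set$genes |>
    select("gene_id", "symbol", "panel_class", "group", "gene_length_kb") |>
    left_join(counts, by = "gene_id") |>
    mutate(n_sv = coalesce(.data$n_sv, 0L),
           svs_per_kb = .data$n_sv / .data$gene_length_kb)
  key <- if (by == "group") per_gene$group else per_gene$panel_class

  cmp_rows <- lapply(comparisons, function(pair) {
    a <- per_gene$svs_per_kb[key == pair[1]]
    b <- per_gene$svs_per_kb[key == pair[2]]
    if (length(a) == 0 || length(b) == 0) {
      warn(paste0("comparison ", pair[1], " vs ", pair[2],
                  " skipped: empty class"))
      return(NULL)
    }
    w <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
    tibble(class_a = pair[1], class_b = pair[2],
           n_a = length(a), n_b = length(b),
           statistic = unname(w$statistic), p_value = w$p.value)
  })
  cmp <- bind_rows(cmp_rows)
  if (adjust && nrow(cmp) > 0) cmp$p_adj <- stats::p.adjust(cmp$p_value, "BH")
  list(per_gene = per_gene, comparisons = cmp)
}
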