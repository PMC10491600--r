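#' Gene models for a pharmacogene panel
#'
#' A `gene_set` bundles gene-level metadata (span, strand, panel class,
#' length in kb) with exon structures and, when available, CDS intervals.
#' Coordinates are 0-based half-open. Interval indexes over gene spans and
#' exons back [gene_interval_query()].
#'
#' @param genes Tibble with columns `gene_id`, `symbol`, `chrom`, `strand`,
#'   `start`, `end`, `panel_class`.
#' @param exons Tibble with columns `gene_id`, `chrom`, `start`, `end`.
#' @param cds Optional tibble like `exons` restricted to coding sequence.
#' @param missing Tibble of panel genes absent from the annotation
#'   (columns `gene`, `panel_class`).
#' @return An object of class `gene_set`.
#' @export
new_gene_set <- function(genes, exons, cds = NULL,
                         missing = tibble(gene = character(),
                                          panel_class = character())) {
  genes <- as_tibble(genes)
  exons <- as_tibble(exons) |> arrange(.data$gene_id, .data$start)
  if (anyDuplicated(genes$gene_id)) abort("duplicate gene_id in gene set")
  check_interval(exons$chrom, exons$start, exons$end)
  # exons of one gene must be pairwise disjoint and on the gene's chromosome
  by_gene <- split(exons, exons$gene_id)
  for (g in by_gene) {
    if (nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)])) {
      abort(paste0("overlapping exons in gene ", g$gene_id[1]))
    }
  }
  genes$gene_length_kb <- (genes$end - genes$start) / 1000
  if (any(genes$gene_length_kb <= 0)) abort("gene span must have length > 0")
  genes$group <- panel_group(genes$panel_class)
  structure(
    list(genes = genes, exons = exons, cds = cds, missing = as_tibble(missing),
         gr_span = as_granges0(genes), gr_exon = as_granges0(exons)),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", nrow(x$genes), " genes, ", nrow(x$exons), " exons",
      if (!is.null(x$cds)) paste0(", ", nrow(x$cds), " CDS segments"),
      "\n", sep = "")
  if (nrow(x$missing) > 0) {
    cat("  panel genes missing from annotation: ",
        paste(x$missing$gene, collapse = ", "), "\n", sep = "")
  }
  print(count(x$genes, .data$group, .data$panel_class))
  invisible(x)
}

# cheap structural checks before handing a GTF to rtracklayer, so malformed
# lines are reported with their line number
validate_gtf_lines <- function(path) {
  lines <- readr::read_lines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield < 9)) {
    bad <- which(body)[which(nfield < 9)[1]]
    abort(paste0("malformed GTF line ", bad, ": expected 9 tab-separated ",
                 "fields, found ", nfield[which(nfield < 9)[1]]))
  }
  invisible(TRUE)
}

#' Load gene models and a pharmacogene panel
#'
#' Reads a GTF/GFF (or BED12) annotation, restricts it to the genes listed in
#' a panel table (gene -> class), and builds a [new_gene_set()]. GTF 1-based
#' inclusive coordinates are converted to 0-based half-open on read. When a
#' gene has several transcripts, the default keeps the canonical (longest by
#' summed exon width) transcript; `transcript = "union"` merges all exons.
#' Panel genes absent from the annotation are collected in `$missing` and
#' reported with a warning, never silently dropped.
#'
#' @param annotation Path to a GTF/GFF or BED12 file.
#' @param panel Path to a TSV with columns `gene` and `class`, or a tibble.
#' @param format `"auto"` (by extension), `"gtf"` or `"bed12"`.
#' @param gene_id_attr GTF attribute holding the gene identifier.
#' @param transcript `"canonical"` (longest) or `"union"` of all transcripts.
#' @param flank Flank in bp added to each side of the gene span when
#'   assigning SVs (default 0: span only).
#' @param keep_cds Extract CDS features from the GTF when present, enabling
#'   UTR-aware classification.
#' @return A `gene_set`.
#' @export
read_gene_models <- function(annotation, panel, format = c("auto", "gtf", "bed12"),
                             gene_id_attr = "gene_id",
                             transcript = c("canonical", "union"),
                             flank = 0L, keep_cds = TRUE) {
  format <- match.arg(format)
  transcript <- match.arg(transcript)
  if (format == "auto") {
    format <- if (grepl("\\.bed1?2?$", annotation, ignore.case = TRUE))
      "bed12" else "gtf"
  }
  panel_tbl <- if (is.character(panel)) {
    readr::read_tsv(panel, show_col_types = FALSE)
  } else as_tibble(panel)
  names(panel_tbl)[1:2] <- c("gene", "panel_class")

  if (format == "gtf") {
    validate_gtf_lines(annotation)
    gr <- rtracklayer::import(annotation, format = "gtf")
    md <- as_tibble(S4Vectors::mcols(gr))
    if (!gene_id_attr %in% names(md)) {
      abort(paste0("GTF attribute '", gene_id_attr, "' not found"))
    }
    feat <- tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = BiocGenerics::start(gr) - 1L,  # to 0-based half-open
      end = BiocGenerics::end(gr),
      strand = as.character(BiocGenerics::strand(gr)),
      type = as.character(md$type),
      gene_id = md[[gene_id_attr]],
      symbol = if ("gene_name" %in% names(md)) md$gene_name else md[[gene_id_attr]],
      transcript_id = if ("transcript_id" %in% names(md)) md$transcript_id else NA_character_
    )
    ex <- filter(feat, .data$type == "exon")
    if (transcript == "canonical" && !all(is.na(ex$transcript_id))) {
      keep_tx <- ex |>
        group_by(.data$gene_id, .data$transcript_id) |>
        summarise(tx_len = sum(.data$end - .data$start), .groups = "drop") |>
        group_by(.data$gene_id) |>
        arrange(desc(.data$tx_len), .data$transcript_id, .by_group = TRUE) |>
        slice(1) |>
        ungroup()
      ex <- semi_join(ex, keep_tx, by = c("gene_id", "transcript_id"))
    }
    exons <- ex |>
      distinct(.data$gene_id, .data$chrom, .data$start, .data$end) |>
      group_by(.data$gene_id, .data$chrom) |>
      arrange(.data$start, .by_group = TRUE) |>
      ungroup()
    # merge any residual overlaps (union mode can produce them)
    exons <- merge_exons(exons)
    cds <- NULL
    if (keep_cds && any(feat$type == "CDS")) {
      cds <- feat |>
        filter(.data$type == "CDS") |>
        distinct(.data$gene_id, .data$chrom, .data$start, .data$end) |>
        merge_exons()
    }
    gene_meta <- feat |>
      distinct(.data$gene_id, .data$symbol, .data$chrom, .data$strand) |>
      distinct(.data$gene_id, .keep_all = TRUE)
  } else {
    gr <- rtracklayer::import(annotation, format = "bed")
    blocks <- rtracklayer::blocks(gr)
    ub <- BiocGenerics::unlist(blocks)
    exons <- tibble(
      gene_id = names(ub),
      chrom = as.character(GenomicRanges::seqnames(ub)),
      start = BiocGenerics::start(ub) - 1L,
      end = BiocGenerics::end(ub)
    )
    gene_meta <- tibble(
      gene_id = gr$name,
      symbol = gr$name,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(BiocGenerics::strand(gr))
    )
    cds <- NULL
  }

  # resolve panel entries by gene_id first, then symbol
  hit_id <- panel_tbl$gene %in% gene_meta$gene_id
  hit_sym <- !hit_id & panel_tbl$gene %in% gene_meta$symbol
  sym2id <- setNames(gene_meta$gene_id, gene_meta$symbol)
  panel_tbl$gene_id <- ifelse(hit_id, panel_tbl$gene,
                              ifelse(hit_sym, sym2id[panel_tbl$gene], NA))
  missing <- panel_tbl |>
    filter(is.na(.data$gene_id)) |>
    select(gene = "gene", panel_class = "panel_class")
  if (nrow(missing) > 0) {
    warn(paste0(nrow(missing), " panel gene(s) missing from annotation: ",
                paste(missing$gene, collapse = ", ")))
  }
  panel_ok <- filter(panel_tbl, !is.na(.data$gene_id))

  span <- exons |>
    group_by(.data$gene_id) |>
    summarise(ex_start = min(.data$start), ex_end = max(.data$end),
              .groups = "drop")
  genes <- panel_ok |>
    left_join(gene_meta, by = "gene_id") |>
    inner_join(span, by = "gene_id") |>
    transmute(.data$gene_id, .data$symbol, .data$chrom, .data$strand,
              start = pmax(0L, .data$ex_start - as.integer(flank)),
              end = .data$ex_end + as.integer(flank),
              .data$panel_class)
  exons <- semi_join(exons, genes, by = "gene_id")
  if (!is.null(cds)) cds <- semi_join(cds, genes, by = "gene_id")
  new_gene_set(genes, exons, cds = cds, missing = missing)
}

# union overlapping exon rows per gene
merge_exons <- function(exons) {
  exons |>
    group_by(.data$gene_id, .data$chrom) |>
    group_modify(function(d, key) {
      ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
      tibble(start = BiocGenerics::start(ir) - 1L, end = BiocGenerics::end(ir))
    }) |>
    ungroup()
}

#' Query genes overlapping an interval
#'
#' Returns one row per gene whose span intersects the query interval, with a
#' flag saying whether any exon is hit. SVs spanning several genes therefore
#' yield one entry per gene.
#'
#' @param gene_set A [new_gene_set()].
#' @param chrom,start,end Query interval, 0-based half-open.
#' @return Tibble with columns `gene_id`, `overlaps_exon`.
#' @export
gene_interval_query <- function(gene_set, chrom, start, end) {
  check_interval(chrom, start, end)
  if (!chrom %in% unique(gene_set$genes$chrom)) {
    return(tibble(gene_id = character(), overlaps_exon = logical()))
  }
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  hit <- S4Vectors::subjectHits(GenomicRanges::findOverlaps(q, gene_set$gr_span))
  if (length(hit) == 0) {
    return(tibble(gene_id = character(), overlaps_exon = logical()))
  }
  ids <- gene_set$genes$gene_id[hit]
  ex_hit <- S4Vectors::subjectHits(GenomicRanges::findOverlaps(q, gene_set$gr_exon))
  ex_genes <- unique(gene_set$exons$gene_id[ex_hit])
  tibble(gene_id = ids, overlaps_exon = ids %in% ex_genes)
}

#' Write / re-read a normalized gene-model TSV
#'
#' One row per exon (and CDS segment when present) with gene-level columns
#' repeated; [read_gene_set_tsv()] reconstructs an identical `gene_set`.
#'
#' @param gene_set A `gene_set`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(gene_set, path) {
  ex <- gene_set$exons |> mutate(feature = "exon")
  if (!is.null(gene_set$cds)) {
    ex <- bind_rows(ex, gene_set$cds |> mutate(feature = "CDS"))
  }
  out <- ex |>
    left_join(gene_set$genes |>
                select("gene_id", "symbol", "strand", gene_start = "start",
                       gene_end = "end", "panel_class"),
              by = "gene_id") |>
    select("gene_id", "symbol", "chrom", "strand", "gene_start", "gene_end",
           "panel_class", "feature", feat_start = "start", feat_end = "end") |>
    arrange(.data$gene_id, .data$feature, .data$feat_start)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_gene_set
#' @export
read_gene_set_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  genes <- d |>
    distinct(.data$gene_id, .data$symbol, .data$chrom, .data$strand,
             start = .data$gene_start, end = .data$gene_end, .data$panel_class)
  exons <- d |>
    filter(.data$feature == "exon") |>
    select("gene_id", "chrom", start = "feat_start", end = "feat_end")
  cds <- d |> filter(.data$feature == "CDS")
  cds <- if (nrow(cds) > 0) {
    select(cds, "gene_id", "chrom", start = "feat_start", end = "feat_end")
  } else NULL
  new_gene_set(genes, exons, cds = cds)
}
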