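# Independent brute-force oracles and tiny fixture builders used across the
# suite. These deliberately avoid the package's own interval machinery.

# union-find over the pairwise "overlapping or within max_dist" relation
brute_cluster <- function(start, end, max_dist = 0) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        gap <- max(start[i], start[j]) - min(end[i], end[j])
        if (gap <= max_dist) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# all-pairs interval overlap scan over a gene set
brute_gene_query <- function(gene_set, start, end) {
  g <- gene_set$genes
  hits <- g$gene_id[g$start < end & start < g$end]
  ex_hit <- vapply(hits, function(id) {
    e <- gene_set$exons[gene_set$exons$gene_id == id, ]
    any(e$start < end & start < e$end)
  }, logical(1))
  data.frame(gene_id = hits, overlaps_exon = unname(ex_hit),
             stringsAsFactors = FALSE)
}

# minimal two-gene fixture: gene A with 3 exons, gene B with 2 exons
toy_gene_set <- function(flanked = FALSE) {
  genes <- tibble::tibble(
    gene_id = c("A", "B"), symbol = c("GENEA", "GENEB"), chrom = "chr1",
    strand = c("+", "-"), start = c(1000L, 20000L), end = c(5000L, 24000L),
    panel_class = c("CYP", "ion_channel")
  )
  exons <- tibble::tibble(
    gene_id = c("A", "A", "A", "B", "B"), chrom = "chr1",
    start = c(1000L, 2500L, 4500L, 20000L, 23500L),
    end = c(1300L, 2800L, 5000L, 20400L, 24000L)
  )
  new_gene_set(genes, exons)
}

# one-row SV tibble in the normalized table layout
toy_sv <- function(sv_id = "sv1", start, end, sv_type = "DEL", af = 0.1,
                   filter = "PASS", mcnv_spectrum = NA_character_,
                   length_bp = NULL, chrom = "chr1") {
  tibble::tibble(
    sv_id = sv_id, chrom = chrom, start = as.integer(start),
    end = as.integer(end), sv_type = sv_type, filter = filter,
    length_bp = length_bp %||% (as.integer(end) - as.integer(start)),
    af = af, af_afr = af, af_amr = af, af_eas = af, af_eur = af, af_oth = af,
    mcnv_spectrum = mcnv_spectrum, singleton = FALSE, type_known = TRUE
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
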