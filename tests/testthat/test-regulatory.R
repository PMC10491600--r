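mk_peak <- function(start, end, tf = "CTCF", score = 500L, obs = 5L,
                    total = 1264L, chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), tf_name = tf,
                 peak_score = as.integer(score),
                 studies_observed = as.integer(obs),
                 studies_total = as.integer(total))
}

noncoding_ann <- function(...) {
  rows <- dplyr::bind_rows(...)
  ann <- annotate_svs(new_sv_table(rows, source = "t"), toy_gene_set())
  ann[!ann$coding, ]
}

test_that("TFBS score and study filters use the documented boundaries", {
  peaks <- dplyr::bind_rows(
    mk_peak(1, 10, score = 199, obs = 3),    # score below 200 -> out
    mk_peak(1, 10, score = 950, obs = 1),    # single-study -> out
    mk_peak(1, 10, score = 200, obs = 2)     # both boundaries inclusive -> in
  )
  kept <- filter_tfbs(peaks)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$peak_score, 200)
  log <- pgx_log(kept)
  expect_equal(log$n[log$reason == "input"], 3)
})

test_that("SV-TF overlap is any-overlap with per-SV TF deduplication", {
  nc <- noncoding_ann(toy_sv("ncd", 1400, 2400, "DEL"))
  peaks <- dplyr::bind_rows(
    mk_peak(1500, 1550, tf = "CTCF"),
    mk_peak(1700, 1750, tf = "CTCF"),     # second peak of the same TF
    mk_peak(1800, 1850, tf = "HNF4A"),
    mk_peak(3000, 3050, tf = "FOS")       # outside the SV
  )
  pairs <- overlap_tfbs(nc, peaks)
  expect_equal(nrow(pairs), 2)
  expect_setequal(pairs$tf_name, c("CTCF", "HNF4A"))
})

test_that("overlap pairs match a brute-force all-pairs intersection", {
  set.seed(31)
  g <- generate_genome(n_genes = 30, seed = 31)
  co <- generate_sv_cohort(list(gene_set = g$gene_set), n_svs = 300, seed = 31)
  ann <- annotate_svs(cluster_sv_table(filter_sv_records(co$svs)), g$gene_set)
  nc <- ann[!ann$coding, ]
  lo <- min(g$gene_set$genes$start); hi <- max(g$gene_set$genes$end)
  peaks <- mk_peak(sample(lo:hi, 150), 0)
  peaks$end <- peaks$start + sample(20:200, 150, replace = TRUE)
  peaks$tf_name <- sample(c("CTCF", "FOS", "SP1"), 150, replace = TRUE)
  got <- overlap_tfbs(nc, peaks)
  want <- list()
  for (i in seq_len(nrow(nc))) {
    for (j in seq_len(nrow(peaks))) {
      if (nc$start[i] < peaks$end[j] && peaks$start[j] < nc$end[i]) {
        want[[length(want) + 1]] <- paste(nc$sv_id[i], nc$gene_id[i],
                                          peaks$tf_name[j])
      }
    }
  }
  expect_setequal(paste(got$sv_id, got$gene_id, got$tf_name),
                  unique(unlist(want)))
})

test_that("restricting the evaluated window to the gene flank drops distal peaks", {
  # gene span recorded with regulatory context [500, 3000); exons inside
  gs <- new_gene_set(
    tibble::tibble(gene_id = "G", symbol = "GENEG", chrom = "chr1",
                   strand = "+", start = 500L, end = 3000L,
                   panel_class = "SLC"),
    tibble::tibble(gene_id = "G", chrom = "chr1",
                   start = c(1000L, 2000L), end = c(1300L, 2300L))
  )
  # non-coding deletion assigned to the gene but stretching far downstream
  nc <- annotate_svs(new_sv_table(toy_sv("long_nc", 2350, 9000, "DEL"),
                                  source = "t"), gs)
  expect_false(any(nc$coding))
  distal <- mk_peak(8000, 8100)
  expect_equal(nrow(overlap_tfbs(nc, distal)), 1)
  expect_equal(nrow(overlap_tfbs(nc, distal, gene_set = gs,
                                 region = "gene_flank", flank = 1000)), 0)
})

test_that("co-expression requires a shared tissue above the threshold", {
  expr <- matrix(0, nrow = 3, ncol = 9,
                 dimnames = list(c("GENEA", "CTCF", "HNF4A"), pgx_tissues()))
  expr["GENEA", "liver"] <- 12
  expr["CTCF", "liver"] <- 8
  expr["GENEA", "brain"] <- 5       # gene in brain, but HNF4A only in liver
  expr["HNF4A", "liver"] <- 0.2     # below threshold everywhere
  pairs <- tibble::tibble(
    sv_id = c("s1", "s1", "s2"), gene_id = "A", symbol = "GENEA",
    tf_name = c("CTCF", "HNF4A", "GHOST_TF"), sv_type = "DEL",
    component = NA_character_, af_used = 0.1,
    af_afr = 0.1, af_amr = 0.1, af_eas = 0.1, af_eur = 0.1, af_oth = 0.1
  )
  hits <- coexpression_filter(pairs, expr)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$tf_name, "CTCF")
  expect_true("liver" %in% hits$tissues_supported[[1]])
  expect_equal(hits$direction_hint, "ablation")
  log <- pgx_log(hits)
  expect_equal(log$n[log$reason == "missing_symbol"], 1)  # GHOST_TF dropped
})

test_that("the regulatory pipeline only ever removes candidates", {
  g <- generate_genome(n_genes = 40, seed = 13)
  co <- generate_sv_cohort(list(gene_set = g$gene_set), n_svs = 400, seed = 13)
  reg <- generate_regulatory_layers(g, co, n_hits = 8, seed = 13)
  ann <- annotate_svs(cluster_sv_table(filter_sv_records(co$svs)), g$gene_set)
  nc <- ann[!ann$coding, ]
  kept_peaks <- filter_tfbs(reg$peaks)
  pairs <- overlap_tfbs(nc, kept_peaks)
  hits <- coexpression_filter(pairs, reg$expr)
  expect_lte(nrow(kept_peaks), nrow(reg$peaks))
  expect_lte(nrow(hits), nrow(pairs))
  # planted (sv, gene, tf) triples with their tissue are recovered exactly
  expect_setequal(paste(hits$sv_id, hits$gene_id, hits$tf_name),
                  paste(reg$truth$sv_id, reg$truth$gene_id, reg$truth$tf_name))
  for (i in seq_len(nrow(reg$truth))) {
    hit <- hits[hits$sv_id == reg$truth$sv_id[i] &
                  hits$tf_name == reg$truth$tf_name[i], ]
    expect_equal(hit$tissues_supported[[1]], reg$truth$tissue[i])
  }
})

test_that("TFBS BED round-trips through its reader", {
  dir <- withr::local_tempdir()
  g <- generate_genome(n_genes = 30, seed = 17)
  co <- generate_sv_cohort(list(gene_set = g$gene_set), n_svs = 300, seed = 17)
  reg <- generate_regulatory_layers(g, co, seed = 17, dir = dir)
  back <- read_tfbs_bed(reg$peaks_path)
  expect_equal(nrow(back), nrow(reg$peaks))
  expect_equal(back$start, reg$peaks$start)
  expect_equal(back$studies_observed, reg$peaks$studies_observed)
  expect_equal(back$studies_total, reg$peaks$studies_total)
  expr_back <- read_expression_matrix(reg$expr_path)
  expect_equal(expr_back, reg$expr)
})
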