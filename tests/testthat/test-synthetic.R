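test_that("generation is byte-identical under the same seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  g1 <- generate_genome(n_genes = 50, seed = 7, dir = d1)
  g2 <- generate_genome(n_genes = 50, seed = 7, dir = d2)
  expect_identical(readLines(g1$gtf_path), readLines(g2$gtf_path))
  expect_identical(readLines(g1$panel_path), readLines(g2$panel_path))
  c1 <- generate_sv_cohort(g1, n_svs = 200, seed = 3, dir = d1)
  c2 <- generate_sv_cohort(g2, n_svs = 200, seed = 3, dir = d2)
  expect_identical(readLines(c1$sv_path), readLines(c2$sv_path))
  expect_identical(c1$truth, c2$truth)
})

test_that("a single one-exon gene yields a minimal valid annotation", {
  dir <- withr::local_tempdir()
  g <- generate_genome(n_genes = 1, exons_per_gene = c(1, 1), seed = 1,
                       dir = dir)
  expect_equal(nrow(g$gene_set$exons), 1)
  gs <- read_gene_models(g$gtf_path, g$panel_path)
  expect_equal(nrow(gs$genes), 1)
})

test_that("infeasible gene packing is rejected", {
  expect_error(generate_genome(n_genes = 100, chrom_length = 50000, seed = 1),
               "pack")
})

test_that("class labels follow the configured mix within binomial bounds", {
  g <- generate_genome(n_genes = 100, seed = 23,
                       class_mix = c(CYP = 0.5, ion_channel = 0.5))
  n_adme <- sum(g$gene_set$genes$panel_class == "CYP")
  # 99% binomial CI around 50/100
  expect_true(abs(n_adme - 50) < 2.58 * sqrt(100 * 0.25))
})

test_that("planted SVs satisfy their geometric definitions", {
  g <- generate_genome(n_genes = 50, seed = 19)
  co <- generate_sv_cohort(g, n_svs = 400, seed = 19)
  svs <- dplyr::as_tibble(co$svs)
  genes <- g$gene_set$genes
  tr <- dplyr::left_join(co$truth,
                         dplyr::select(svs, sv_id, start, end), by = "sv_id")
  wg <- tr[tr$kind %in% c("whole_gene_dup", "mcnv_dup_whole_gene"), ]
  for (i in seq_len(nrow(wg))) {
    gene <- genes[genes$gene_id == wg$gene_id[i], ]
    expect_true(wg$start[i] < gene$start && wg$end[i] > gene$end)
  }
  # frequencies populate both rarity strata
  expect_true(any(tr$af >= 0.01, na.rm = TRUE))
  expect_true(any(tr$af < 0.01, na.rm = TRUE))
  # quota infeasibility errors name the quota
  expect_error(
    generate_sv_cohort(g, n_svs = 400,
                       quotas = list(whole_gene_dup = 60), seed = 1),
    "whole_gene_dup"
  )
})

test_that("a point-mass common deletion classifies downstream as common LOF", {
  g <- generate_genome(n_genes = 20, seed = 29)
  co <- generate_sv_cohort(
    g, n_svs = 30,
    quotas = list(exonic_del = 1),
    af_model = list(shape = c(0.2, 20), common_mass = 0.845, p_common = 1),
    seed = 29
  )
  ann <- annotate_svs(cluster_sv_table(filter_sv_records(co$svs)), g$gene_set)
  planted <- co$truth[co$truth$kind == "exonic_del", ]
  row <- ann[ann$sv_id == planted$sv_id, ]
  expect_equal(row$functional_class, "LOF")
  expect_equal(row$rarity, "common")
  expect_equal(row$af_used, 0.845)
})

test_that("the end-to-end functional-class confusion matrix is diagonal", {
  g <- generate_genome(n_genes = 50, seed = 37)
  co <- generate_sv_cohort(g, n_svs = 450, seed = 37)
  ann <- annotate_svs(cluster_sv_table(filter_sv_records(co$svs)), g$gene_set)
  tr <- co$truth[!co$truth$kind %in% c("filler", "artifact"), ]
  got <- dplyr::as_tibble(ann)[, c("sv_id", "gene_id", "component",
                                   "functional_class")]
  chk <- dplyr::left_join(
    tr, got,
    by = c("sv_id", "gene_id", "component"),
    suffix = c("_true", "_got")
  )
  expect_true(all(!is.na(chk$functional_class_got)))
  expect_equal(chk$functional_class_got, chk$functional_class_true)
  # fillers and artifacts never reach the panel annotation
  outside <- co$truth$sv_id[co$truth$kind %in% c("filler", "artifact")]
  expect_false(any(ann$sv_id %in% outside))
})

test_that("the eQTL matched share tracks match_fraction", {
  g <- generate_genome(n_genes = 50, seed = 41)
  co <- generate_sv_cohort(g, n_svs = 450, seed = 41)
  eq <- generate_eqtls(g, co, n_eqtls = 400, match_fraction = 0.23, seed = 41)
  share <- mean(!is.na(eq$truth$sv_id))
  # 99% binomial CI around 0.23 at n = 400
  expect_true(abs(share - 0.23) < 2.58 * sqrt(0.23 * 0.77 / 400))
  all_m <- generate_eqtls(g, co, n_eqtls = 50, match_fraction = 1, seed = 41)
  expect_true(all(!is.na(all_m$truth$sv_id)))
  none <- generate_eqtls(g, co, n_eqtls = 50, match_fraction = 0, seed = 41)
  expect_true(all(is.na(none$truth$sv_id)))
})

test_that("regulatory layers straddle the filter boundaries as designed", {
  g <- generate_genome(n_genes = 50, seed = 43)
  co <- generate_sv_cohort(g, n_svs = 400, seed = 43)
  reg <- generate_regulatory_layers(g, co, n_hits = 10, seed = 43)
  kept <- filter_tfbs(reg$peaks)
  # every planted peak survives, all decoys fail score/study/location
  expect_gte(nrow(kept), 10)
  expect_true(any(reg$peaks$peak_score < 200))
  expect_true(any(reg$peaks$studies_observed == 1))
  # the expression design realizes the planted triples exactly at threshold 1
  for (i in seq_len(nrow(reg$truth))) {
    expect_gte(reg$expr[reg$truth$symbol[i], reg$truth$tissue[i]], 1)
    expect_gte(reg$expr[reg$truth$tf_name[i], reg$truth$tissue[i]], 1)
  }
})
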