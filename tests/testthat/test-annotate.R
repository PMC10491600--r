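# gene A of toy_gene_set: span [1000, 5000), exons [1000,1300) [2500,2800)
# [4500,5000)

annotate_one <- function(sv_rows, gs = toy_gene_set()) {
  annotate_svs(new_sv_table(sv_rows, source = "test"), gs)
}

test_that("coding status is exon intersection; insertions count by their point", {
  gs <- toy_gene_set()
  ann <- annotate_one(dplyr::bind_rows(
    toy_sv("del_exon", 2400, 2600, "DEL"),        # covers part of exon 2
    toy_sv("del_intron", 1400, 2400, "DEL"),      # fully intronic
    toy_sv("ins_exon", 2600, 2601, "INS", length_bp = 120),
    toy_sv("ins_upstream", 995, 996, "INS", length_bp = 80)  # 5 bp before gene
  ), gs)
  expect_true(ann$coding[ann$sv_id == "del_exon"])
  expect_false(ann$coding[ann$sv_id == "del_intron"])
  expect_true(ann$coding[ann$sv_id == "ins_exon"])
  expect_false("ins_upstream" %in% ann$sv_id)  # outside the span entirely
})

test_that("functional classes follow the LOF/IGD rule set", {
  ann <- annotate_one(dplyr::bind_rows(
    toy_sv("lof_del", 900, 3000, "DEL"),            # spans exons 1-2
    toy_sv("igd_dup", 900, 5100, "DUP"),            # contains the gene span
    toy_sv("fs_dup", 2450, 2600, "DUP"),            # 100 exonic bases, 100 %% 3 != 0
    toy_sv("if_dup", 2450, 2599, "DUP"),            # 99 exonic bases, in frame
    toy_sv("lof_inv", 1500, 6000, "INV"),           # breakpoint in intron 1, spans exons
    toy_sv("wg_inv", 900, 6000, "INV"),             # both breakpoints outside
    toy_sv("cpx", 2400, 2900, "CPX"),
    toy_sv("nc_del", 1400, 1600, "DEL")
  ))
  cls <- setNames(ann$functional_class, ann$sv_id)
  expect_equal(cls[["lof_del"]], "LOF")
  expect_equal(cls[["igd_dup"]], "IGD")
  expect_equal(cls[["fs_dup"]], "LOF")
  expect_equal(cls[["if_dup"]], "UNKNOWN")
  expect_equal(cls[["lof_inv"]], "LOF")
  expect_equal(cls[["wg_inv"]], "UNKNOWN")
  expect_equal(cls[["cpx"]], "UNKNOWN")
  expect_equal(cls[["nc_del"]], "NONE")
})

test_that("MCNV records decompose into classified DEL/DUP component rows", {
  ann <- annotate_one(dplyr::bind_rows(
    toy_sv("mc_del", 2400, 2900, "MCNV", filter = "MULTIALLELIC",
           mcnv_spectrum = "0:0.845,2:0.155"),
    toy_sv("mc_both", 900, 5100, "MCNV", filter = "MULTIALLELIC",
           mcnv_spectrum = "0:0.10,2:0.70,3:0.20"),
    toy_sv("mc_ref", 2400, 2900, "MCNV", filter = "MULTIALLELIC",
           mcnv_spectrum = "2:1.0")
  ))
  d <- ann[ann$sv_id == "mc_del", ]
  expect_equal(d$component, "DEL")
  expect_equal(d$functional_class, "LOF")
  expect_equal(d$af_used, 0.845)
  expect_equal(d$rarity, "common")
  b <- ann[ann$sv_id == "mc_both", ]
  expect_setequal(b$component, c("DEL", "DUP"))
  expect_equal(b$functional_class[b$component == "DEL"], "LOF")
  expect_equal(b$functional_class[b$component == "DUP"], "IGD")
  # population frequencies split proportionally to component shares
  expect_equal(sum(b$af_afr), 0.1, tolerance = 1e-12)
  # reference-only MCNV yields no rows but is logged
  expect_false("mc_ref" %in% ann$sv_id)
  log <- pgx_log(ann)
  expect_equal(log$n[log$reason == "reference_only_mcnv"], 1)
})

test_that("UTR-only hits become UNKNOWN when CDS annotation is present", {
  gs <- toy_gene_set()
  # CDS excludes the first 100 bp of exon 1 (5' UTR)
  gs_cds <- new_gene_set(gs$genes, gs$exons,
                         cds = tibble::tibble(
                           gene_id = c("A", "A", "A"), chrom = "chr1",
                           start = c(1100L, 2500L, 4500L),
                           end = c(1300L, 2800L, 5000L)))
  ann <- annotate_svs(new_sv_table(dplyr::bind_rows(
    toy_sv("utr_del", 1000, 1050, "DEL"),
    toy_sv("cds_del", 1150, 1250, "DEL")
  ), source = "t"), gs_cds)
  expect_equal(ann$functional_class[ann$sv_id == "utr_del"], "UNKNOWN")
  expect_equal(ann$functional_class[ann$sv_id == "cds_del"], "LOF")
})

test_that("a multi-gene SV is annotated once per gene", {
  ann <- annotate_one(toy_sv("big", 900, 24100, "DEL"))
  expect_equal(nrow(ann), 2)
  expect_setequal(ann$gene_id, c("A", "B"))
  expect_true(all(ann$functional_class == "LOF"))
})

test_that("rarity uses the reported SV frequency with a 1% boundary", {
  expect_equal(rarity_class(c(0.010, 0.0099, 0.845)),
               c("common", "rare", "common"))
})

test_that("every annotated row has exactly one functional class summing to total", {
  g <- generate_genome(n_genes = 40, seed = 3)
  co <- generate_sv_cohort(list(gene_set = g$gene_set), n_svs = 400, seed = 3)
  ann <- annotate_svs(cluster_sv_table(filter_sv_records(co$svs)), g$gene_set)
  expect_true(all(ann$functional_class %in% c("LOF", "IGD", "UNKNOWN", "NONE")))
  tab <- table(ann$functional_class)
  expect_equal(sum(tab), nrow(ann))
  expect_true(all(!ann$coding == (ann$functional_class == "NONE")))
})

test_that("per-kb densities are exact and class comparisons behave", {
  # 40 genes of 10 kb split into two classes
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:40), symbol = sprintf("g%02d", 1:40),
    chrom = "chr1", strand = "+",
    start = seq(0L, by = 20000L, length.out = 40),
    end = seq(10000L, by = 20000L, length.out = 40),
    panel_class = rep(c("CYP", "ion_channel"), each = 20)
  )
  exons <- tibble::tibble(gene_id = genes$gene_id, chrom = "chr1",
                          start = genes$start, end = genes$start + 200L)
  gs <- new_gene_set(genes, exons)

  fake_ann <- function(counts) {
    rows <- lapply(seq_along(counts), function(i) {
      n <- counts[i]
      if (n == 0) return(NULL)
      tibble::tibble(gene_id = genes$gene_id[i],
                     sv_id = sprintf("%s_sv%d", genes$gene_id[i], seq_len(n)))
    })
    dplyr::bind_rows(rows)
  }
  # exact normalization: 5 SVs in a 10 kb gene -> 0.5 SVs per kb
  d0 <- density_table(fake_ann(c(5, rep(0, 39))), gs)
  expect_equal(d0$per_gene$svs_per_kb[d0$per_gene$gene_id == "g01"], 0.5)
  expect_equal(sum(d0$per_gene$n_sv), 5)

  # identical distributions -> rank-sum p near 1
  set.seed(1)
  counts_null <- rep(c(3, 5, 7, 9), 10)  # same multiset in both classes
  dn <- density_table(fake_ann(counts_null), gs,
                      comparisons = list(c("ADME", "drug_target")))
  expect_gt(dn$comparisons$p_value, 0.5)

  # planted 2x density shift is detected
  set.seed(2)
  counts_shift <- c(stats::rpois(20, 12), stats::rpois(20, 6))
  ds <- density_table(fake_ann(counts_shift), gs)
  expect_lt(ds$comparisons$p_value, 0.01)

  # empty class comparison is skipped with a warning
  expect_warning(
    density_table(fake_ann(counts_null), gs,
                  comparisons = list(c("ADME", "olfactory"))),
    "empty class"
  )
})
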