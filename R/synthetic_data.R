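# Synthetic input generator: emulates every pipeline input (gene annotation,
# cohort SV table, TFBS peaks, expression matrix, eQTL catalog) with planted
# ground truth, so every stage is testable without external downloads.

default_class_mix <- function() {
  c(NR = 0.04, CYP = 0.06, SLC = 0.08, ABC = 0.04,
    phase1 = 0.08, phase2 = 0.08,
    ion_channel = 0.15, membrane_receptor = 0.20, enzyme = 0.17,
    transporter = 0.10)
}

#' Generate a synthetic gene annotation with panel classes
#'
#' Places non-overlapping genes with valid exon structures along one
#' chromosome and assigns panel classes from a configurable mix (defaults
#' weight ADME families and drug-target classes roughly as a 908-gene panel
#' of 344 ADME genes and 564 drug targets would). Fully deterministic under
#' `seed`.
#'
#' @param n_genes Number of genes.
#' @param exons_per_gene Integer range (min, max) of exons per gene.
#' @param class_mix Named probability vector over panel classes.
#' @param chrom Chromosome name.
#' @param chrom_length Optional chromosome length; generation aborts if the
#'   genes cannot be packed into it.
#' @param seed RNG seed.
#' @param dir If given, a GTF and a panel TSV are written there.
#' @return List with `gene_set`, and (when `dir` is given) `gtf_path`,
#'   `panel_path`.
#' @export
generate_genome <- function(n_genes = 50, exons_per_gene = c(2, 8),
                            class_mix = default_class_mix(),
                            chrom = "chr1", chrom_length = NULL,
                            seed = 1, dir = NULL) {
  stopifnot(n_genes >= 1)
  set.seed(seed)
  classes <- sample(names(class_mix), n_genes, replace = TRUE,
                    prob = class_mix)
  cursor <- 10000L
  genes <- vector("list", n_genes)
  exons <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    gid <- sprintf("G%03d", i)
    n_ex <- sample(seq(exons_per_gene[1], exons_per_gene[2]), 1)
    ex_w <- sample(100:300, n_ex, replace = TRUE)
    in_w <- if (n_ex > 1) sample(500:2000, n_ex - 1, replace = TRUE) else integer()
    starts <- cursor + c(0L, cumsum(ex_w[-n_ex] + in_w))
    ends <- starts + ex_w
    exons[[i]] <- tibble(gene_id = gid, chrom = chrom,
                         start = starts, end = ends)
    genes[[i]] <- tibble(gene_id = gid, symbol = sprintf("GENE%03d", i),
                         chrom = chrom,
                         strand = sample(c("+", "-"), 1),
                         start = starts[1], end = ends[n_ex],
                         panel_class = classes[i])
    cursor <- ends[n_ex] + sample(5000:20000, 1)
    if (!is.null(chrom_length) && cursor > chrom_length) {
      abort(paste0("cannot pack ", n_genes, " genes into a chromosome of ",
                   chrom_length, " bp"))
    }
  }
  gs <- new_gene_set(bind_rows(genes), bind_rows(exons))
  out <- list(gene_set = gs)
  if (!is.null(dir)) {
    out$gtf_path <- file.path(dir, "genes.gtf")
    out$panel_path <- file.path(dir, "panel.tsv")
    write_synthetic_gtf(gs, out$gtf_path)
    readr::write_tsv(tibble(gene = gs$genes$gene_id,
                            class = gs$genes$panel_class), out$panel_path)
  }
  out
}

# GTF emitter for the synthetic annotation (1-based inclusive on write)
write_synthetic_gtf <- function(gene_set, path) {
  lines <- character(0)
  for (i in seq_len(nrow(gene_set$genes))) {
    g <- gene_set$genes[i, ]
    ex <- gene_set$exons[gene_set$exons$gene_id == g$gene_id, ]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s.t1"; gene_name "%s";',
                     g$gene_id, g$gene_id, g$symbol)
    lines <- c(
      lines,
      paste(g$chrom, "synth", "gene", g$start + 1, g$end, ".", g$strand, ".",
            sprintf('gene_id "%s"; gene_name "%s";', g$gene_id, g$symbol),
            sep = "\t"),
      paste(g$chrom, "synth", "transcript", g$start + 1, g$end, ".",
            g$strand, ".", attrs, sep = "\t"),
      paste(ex$chrom, "synth", "exon", ex$start + 1, ex$end, ".", g$strand,
            ".", attrs, sep = "\t")
    )
  }
  readr::write_lines(lines, path)
  invisible(path)
}

# allele-frequency model: rare-heavy Beta plus common point masses, so both
# rarity strata are populated
draw_af <- function(n, af_model) {
  common <- runif(n) < af_model$p_common
  af <- pmin(0.9, pmax(5e-4, rbeta(n, af_model$shape[1], af_model$shape[2])))
  af[common] <- sample(af_model$common_mass, sum(common), replace = TRUE)
  af
}

# population frequencies jittered around the global value on the logit scale
pop_afs <- function(af, sd = 0.5) {
  m <- vapply(pgx_populations(), function(p) {
    stats::plogis(stats::qlogis(pmin(pmax(af, 1e-6), 1 - 1e-6)) +
                    rnorm(length(af), 0, sd))
  }, numeric(length(af)))
  matrix(m, nrow = length(af), dimnames = list(NULL, pgx_populations()))
}

default_quotas <- function() {
  list(exonic_del = 15, whole_gene_dup = 8, exonic_ins = 12,
       intronic_del = 20, intronic_ins = 10,
       partial_dup_frameshift = 6, partial_dup_inframe = 6,
       inv_breakpoint = 5, inv_whole_gene = 4, cpx_exonic = 5,
       mcnv_del = 5, mcnv_dup_whole_gene = 5)
}

# geometric construction of one planted SV inside/around a gene; returns
# interval, type, spectrum and the truth the pipeline must recover
plant_sv <- function(kind, gene, exons) {
  n_ex <- nrow(exons)
  e1 <- exons[1, ]
  mk <- function(type, start, end, coding, class, component = NA_character_,
                 length_bp = NULL) {
    list(sv_type = type, start = as.integer(start), end = as.integer(end),
         coding = coding, functional_class = class, component = component,
         length_bp = length_bp %||% as.integer(end - start))
  }
  # interior of the first intron (exists: genes have >= 2 exons when intronic
  # or inversion plants are requested)
  intron1 <- if (n_ex > 1) c(exons$end[1], exons$start[2]) else NULL
  intron_last <- if (n_ex > 1) c(exons$end[n_ex - 1], exons$start[n_ex]) else NULL
  switch(
    kind,
    exonic_del = {
      w <- max(1L, min(60L, e1$end - e1$start - 4L))
      mk("DEL", e1$start + 2L, e1$start + 2L + w, TRUE, "LOF")
    },
    exonic_ins = {
      pos <- e1$start + (e1$end - e1$start) %/% 2
      mk("INS", pos, pos + 1L, TRUE, "LOF", length_bp = sample(60:400, 1))
    },
    whole_gene_dup = {
      pad <- sample(150:300, 1)
      mk("DUP", gene$start - pad, gene$end + pad, TRUE, "IGD")
    },
    intronic_del = {
      # first half of the first intron, margins keep plants disjoint
      half <- intron1[1] + (intron1[2] - intron1[1]) %/% 2
      w <- min(200L, half - intron1[1] - 6L)
      mk("DEL", intron1[1] + 3L, intron1[1] + 3L + w, FALSE, "NONE")
    },
    intronic_ins = {
      pos <- intron_last[2] - 10L
      mk("INS", pos, pos + 1L, FALSE, "NONE", length_bp = sample(60:400, 1))
    },
    partial_dup_frameshift = {
      b <- 3L * sample(5:20, 1) + 1L          # not a multiple of 3
      b <- min(b, e1$end - e1$start - 2L)
      if (b %% 3 == 0) b <- b - 1L
      mk("DUP", e1$start - 7L, e1$start + b, TRUE, "LOF")
    },
    partial_dup_inframe = {
      b <- 3L * sample(5:20, 1)
      b <- b - (b %% 3)
      b <- min(b, (e1$end - e1$start - 2L) %/% 3 * 3L)
      mk("DUP", e1$start - 7L, e1$start + b, TRUE, "UNKNOWN")
    },
    inv_breakpoint = {
      mk("INV", intron1[1] + 5L, gene$end + 300L, TRUE, "LOF")
    },
    inv_whole_gene = {
      mk("INV", gene$start - 300L, gene$end + 300L, TRUE, "UNKNOWN")
    },
    cpx_exonic = {
      mk("CPX", e1$start - 3L, e1$end + 3L, TRUE, "UNKNOWN")
    },
    mcnv_del = {
      w <- max(1L, min(80L, e1$end - e1$start - 4L))
      mk("MCNV", e1$start + 2L, e1$start + 2L + w, TRUE, "LOF", "DEL")
    },
    mcnv_dup_whole_gene = {
      pad <- sample(150:300, 1)
      mk("MCNV", gene$start - pad, gene$end + pad, TRUE, "IGD", "DUP")
    },
    abort(paste0("unknown plant kind '", kind, "'"))
  )
}

#' Generate a synthetic cohort SV table with planted ground truth
#'
#' Plants SVs with known gene assignment, coding status and functional class
#' according to `quotas` (each quota names a geometric construction, e.g.
#' `whole_gene_dup` strictly contains its gene span), fills the rest of the
#' cohort with intergenic SVs that never touch the panel, and adds records
#' that the ingest filters must remove (non-PASS filter statuses, unresolved
#' breakpoint junctions, reciprocal translocations). Allele frequencies come
#' from a rare-heavy Beta(0.2, 20) mixed with common point masses; population
#' frequencies are logit-jittered around the global value. Deterministic
#' under `seed`.
#'
#' @param genome Output of [generate_genome()].
#' @param n_svs Total records including fillers and filter-fodder.
#' @param quotas Named list of planted-kind counts (see
#'   `pgxsv:::default_quotas()`).
#' @param af_model List with `shape` (Beta parameters), `common_mass`
#'   (common-AF point masses) and `p_common` (their mixture weight).
#' @param n_artifacts Records carrying removal reasons (split between bad
#'   filter status, unresolved junctions and translocations).
#' @param seed RNG seed.
#' @param dir If given, the SV TSV and a truth JSON are written there.
#' @return List with `svs` (an `sv_table`) and `truth` (one row per record:
#'   `sv_id`, `kind`, `gene_id`, `coding`, `functional_class`, `component`,
#'   `af`, `retained`, `in_panel`).
#' @export
generate_sv_cohort <- function(genome, n_svs = 500, quotas = default_quotas(),
                               af_model = list(shape = c(0.2, 20),
                                               common_mass = c(0.054, 0.259, 0.845),
                                               p_common = 0.1),
                               n_artifacts = 4, seed = 1, dir = NULL) {
  set.seed(seed)
  gs <- genome$gene_set
  genes <- gs$genes
  n_planted <- sum(unlist(quotas))
  if (n_svs < n_planted + n_artifacts) {
    abort("n_svs too small for the requested quotas")
  }

  # round-robin gene assignment per kind; kinds needing introns use
  # multi-exon genes
  multi <- genes$gene_id[genes$gene_id %in%
                           (count(gs$exons, .data$gene_id) |>
                              filter(.data$n >= 2) |> pull(.data$gene_id))]
  recs <- list(); truth <- list(); idx <- 0L
  # kinds whose intervals can overlap within a gene must use disjoint genes
  # per SV type, or genome-wide clustering would merge them and corrupt the
  # planted truth
  conflict_types <- c("DUP", "INV", "MCNV")
  kind_type <- c(exonic_del = "DEL", whole_gene_dup = "DUP",
                 exonic_ins = "INS", intronic_del = "DEL",
                 intronic_ins = "INS", partial_dup_frameshift = "DUP",
                 partial_dup_inframe = "DUP", inv_breakpoint = "INV",
                 inv_whole_gene = "INV", cpx_exonic = "CPX",
                 mcnv_del = "MCNV", mcnv_dup_whole_gene = "MCNV")
  used_by_type <- list()
  for (kind in names(quotas)) {
    k <- quotas[[kind]]
    if (k == 0) next
    pool <- if (kind %in% c("intronic_del", "intronic_ins", "inv_breakpoint"))
      multi else genes$gene_id
    typ <- kind_type[[kind]]
    if (typ %in% conflict_types) {
      pool <- setdiff(pool, used_by_type[[typ]])
    }
    if (length(pool) < k) {
      abort(paste0("quota '", kind, "' infeasible: needs ", k,
                   " genes, only ", length(pool), " eligible"))
    }
    target <- sample(pool, k)
    if (typ %in% conflict_types) {
      used_by_type[[typ]] <- c(used_by_type[[typ]], target)
    }
    for (g_id in target) {
      idx <- idx + 1L
      gene <- genes[genes$gene_id == g_id, ]
      ex <- gs$exons[gs$exons$gene_id == g_id, ]
      p <- plant_sv(kind, gene, ex)
      af <- draw_af(1, af_model)
      spec <- NA_character_
      if (p$sv_type == "MCNV") {
        spec <- if (p$component == "DEL") {
          sprintf("0:%s,2:%s", af, 1 - af)
        } else sprintf("2:%s,3:%s", 1 - af, af)
      }
      pa <- pop_afs(af)
      recs[[idx]] <- tibble(
        sv_id = sprintf("sv%04d", idx), chrom = gene$chrom,
        start = p$start, end = p$end, sv_type = p$sv_type,
        filter = if (p$sv_type == "MCNV") "MULTIALLELIC" else "PASS",
        length_bp = p$length_bp, af = af,
        af_afr = pa[1, "AFR"], af_amr = pa[1, "AMR"], af_eas = pa[1, "EAS"],
        af_eur = pa[1, "EUR"], af_oth = pa[1, "OTH"],
        mcnv_spectrum = spec, singleton = FALSE
      )
      truth[[idx]] <- tibble(
        sv_id = recs[[idx]]$sv_id, kind = kind, gene_id = g_id,
        coding = p$coding, functional_class = p$functional_class,
        component = p$component, af = af, retained = TRUE, in_panel = TRUE
      )
    }
  }

  # intergenic fillers: placed in the gaps between genes with 500 bp margins
  # so they never touch the panel nor merge with planted SVs
  gaps <- tibble(start = head(genes$end, -1) + 500L,
                 end = tail(genes$start, -1) - 500L) |>
    filter(.data$end - .data$start > 1000)
  n_fill <- n_svs - n_planted - n_artifacts
  fill_types <- sample(c("DEL", "DUP", "INS", "INV", "CPX"), n_fill,
                       replace = TRUE, prob = c(0.35, 0.25, 0.2, 0.1, 0.1))
  for (j in seq_len(n_fill)) {
    idx <- idx + 1L
    gap <- gaps[sample(nrow(gaps), 1), ]
    w <- sample(60:400, 1)
    s <- sample(seq(gap$start, gap$end - w - 1), 1)
    typ <- fill_types[j]
    af <- draw_af(1, af_model)
    pa <- pop_afs(af)
    is_ins <- typ == "INS"
    recs[[idx]] <- tibble(
      sv_id = sprintf("sv%04d", idx), chrom = genes$chrom[1],
      start = s, end = if (is_ins) s + 1L else s + w, sv_type = typ,
      filter = "PASS", length_bp = w, af = af,
      af_afr = pa[1, "AFR"], af_amr = pa[1, "AMR"], af_eas = pa[1, "EAS"],
      af_eur = pa[1, "EUR"], af_oth = pa[1, "OTH"],
      mcnv_spectrum = NA_character_, singleton = af < 1e-3
    )
    truth[[idx]] <- tibble(
      sv_id = recs[[idx]]$sv_id, kind = "filler", gene_id = NA_character_,
      coding = FALSE, functional_class = NA_character_,
      component = NA_character_, af = af, retained = TRUE, in_panel = FALSE
    )
  }

  # filter-fodder: bad filter status, unresolved junctions, translocations
  art <- tibble(
    sv_type = rep(c("DEL", "BND_UNRESOLVED", "CTX"),
                  length.out = n_artifacts),
    filter = rep(c("LOW_CALL_RATE", "PASS", "PASS"), length.out = n_artifacts)
  )
  for (j in seq_len(n_artifacts)) {
    idx <- idx + 1L
    gap <- gaps[sample(nrow(gaps), 1), ]
    s <- sample(seq(gap$start, gap$end - 200), 1)
    recs[[idx]] <- tibble(
      sv_id = sprintf("sv%04d", idx), chrom = genes$chrom[1],
      start = s, end = s + 100L, sv_type = art$sv_type[j],
      filter = art$filter[j], length_bp = 100L, af = draw_af(1, af_model),
      af_afr = NA_real_, af_amr = NA_real_, af_eas = NA_real_,
      af_eur = NA_real_, af_oth = NA_real_,
      mcnv_spectrum = NA_character_, singleton = FALSE
    )
    truth[[idx]] <- tibble(
      sv_id = recs[[idx]]$sv_id, kind = "artifact", gene_id = NA_character_,
      coding = FALSE, functional_class = NA_character_,
      component = NA_character_, af = NA_real_, retained = FALSE,
      in_panel = FALSE
    )
  }

  d <- normalize_sv_records(bind_rows(recs))
  svs <- new_sv_table(d, source = "synthetic")
  truth <- bind_rows(truth)
  out <- list(svs = svs, truth = truth)
  if (!is.null(dir)) {
    out$sv_path <- file.path(dir, "svs.tsv")
    out$truth_path <- file.path(dir, "truth.json")
    write_sv_table(svs, out$sv_path)
    jsonlite::write_json(truth, out$truth_path, digits = NA)
  }
  out
}

#' Generate TFBS peaks and an expression matrix with planted regulatory hits
#'
#' Picks planted intronic deletions as regulatory SVs: each gets one peak
#' strictly inside its interval (score >= 200, >= 2 studies) for a chosen TF,
#' and the expression matrix raises that (gene, TF) pair above the expression
#' threshold in exactly one chosen tissue. Decoy peaks straddle the filter
#' boundaries: sub-200 scores inside other non-coding SVs, single-study
#' observations with high scores, and intergenic peaks that overlap nothing.
#'
#' @param genome Output of [generate_genome()].
#' @param cohort Output of [generate_sv_cohort()].
#' @param tfs TF names to draw from.
#' @param n_hits Number of planted (SV, gene, TF, tissue) truths.
#' @param tissues Tissue panel.
#' @param threshold Expression threshold the design realizes exactly.
#' @param seed RNG seed.
#' @param dir If given, peaks BED and expression TSV are written there.
#' @return List with `peaks`, `expr` (matrix) and `truth`
#'   (`sv_id`, `gene_id`, `symbol`, `tf_name`, `tissue`).
#' @export
generate_regulatory_layers <- function(genome, cohort,
                                       tfs = c("CTCF", "RAD21", "FOS", "JUND",
                                               "HNF4A", "RXRA", "SP1", "NR3C1"),
                                       n_hits = 10, tissues = pgx_tissues(),
                                       threshold = 1, seed = 1, dir = NULL) {
  set.seed(seed)
  gs <- genome$gene_set
  cand <- cohort$truth |> filter(.data$kind == "intronic_del")
  if (nrow(cand) < n_hits) {
    abort("not enough intronic deletions planted for the requested n_hits")
  }
  cand <- cand[seq_len(n_hits), ]
  svs <- as_tibble(cohort$svs)
  sym <- setNames(gs$genes$symbol, gs$genes$gene_id)

  peaks <- list(); truth <- list()
  for (i in seq_len(n_hits)) {
    sv <- svs[svs$sv_id == cand$sv_id[i], ]
    tf <- tfs[(i - 1) %% length(tfs) + 1]
    tis <- tissues[(i - 1) %% length(tissues) + 1]
    peaks[[i]] <- tibble(
      chrom = sv$chrom, start = sv$start + 2L,
      end = min(sv$end - 2L, sv$start + 52L),
      tf_name = tf, peak_score = sample(200:1000, 1),
      studies_observed = sample(2:40, 1), studies_total = 1264L
    )
    truth[[i]] <- tibble(sv_id = sv$sv_id, gene_id = cand$gene_id[i],
                         symbol = unname(sym[cand$gene_id[i]]),
                         tf_name = tf, tissue = tis)
  }
  truth <- bind_rows(truth)

  # decoys: low score, single study, and intergenic placements
  others <- cohort$truth |>
    filter(.data$kind == "intronic_del") |>
    slice(-seq_len(min(n_hits, nrow(cand))))
  decoys <- list()
  for (i in seq_len(nrow(others))) {
    sv <- svs[svs$sv_id == others$sv_id[i], ]
    decoys[[length(decoys) + 1]] <- tibble(
      chrom = sv$chrom, start = sv$start + 2L,
      end = min(sv$end - 2L, sv$start + 52L),
      tf_name = sample(tfs, 1), peak_score = sample(50:199, 1),
      studies_observed = sample(2:10, 1), studies_total = 1264L
    )
  }
  decoys[[length(decoys) + 1]] <- tibble(
    chrom = svs$chrom[1], start = 100L, end = 200L,
    tf_name = tfs[1], peak_score = 950L,
    studies_observed = 1L, studies_total = 1264L
  )
  decoys[[length(decoys) + 1]] <- tibble(
    chrom = svs$chrom[1], start = 300L, end = 400L,
    tf_name = tfs[1], peak_score = 850L,
    studies_observed = 5L, studies_total = 1264L
  )
  peaks <- bind_rows(c(peaks, decoys))

  symbols <- unique(c(gs$genes$symbol, tfs))
  expr <- matrix(runif(length(symbols) * length(tissues), 0, threshold / 2),
                 nrow = length(symbols),
                 dimnames = list(symbols, tissues))
  for (i in seq_len(nrow(truth))) {
    expr[truth$symbol[i], truth$tissue[i]] <- runif(1, 2 * threshold, 50)
    expr[truth$tf_name[i], truth$tissue[i]] <- runif(1, 2 * threshold, 50)
  }

  out <- list(peaks = peaks, expr = expr, truth = truth)
  if (!is.null(dir)) {
    out$peaks_path <- file.path(dir, "tfbs.bed")
    out$expr_path <- file.path(dir, "expression.tsv")
    readr::write_tsv(
      peaks |> mutate(studies = paste0(.data$studies_observed, "/",
                                       .data$studies_total)) |>
        select("chrom", "start", "end", "tf_name", "peak_score", "studies"),
      out$peaks_path
    )
    readr::write_tsv(bind_cols(tibble(symbol = rownames(expr)),
                               as_tibble(expr)), out$expr_path)
  }
  out
}

#' Generate an SV-eQTL catalog with a controlled matched share
#'
#' A `match_fraction` share of eQTLs copy a cohort SV interval exactly (same
#' type, reciprocal overlap 1); the rest are shifted by more than 100 bp so
#' that neither the breakpoint-proximity nor the >99%-overlap criterion can
#' hold against their source SV.
#'
#' @param genome Output of [generate_genome()].
#' @param cohort Output of [generate_sv_cohort()].
#' @param n_eqtls Number of eQTL records.
#' @param match_fraction Share of records that match a cohort SV.
#' @param tissues Tissue names to sample from.
#' @param seed RNG seed.
#' @param dir If given, the eQTL TSV is written there.
#' @return List with `eqtls` (tibble with `eqtl_id`) and `truth`
#'   (`eqtl_id`, `sv_id` of the intended match or `NA`).
#' @export
generate_eqtls <- function(genome, cohort, n_eqtls = 100,
                           match_fraction = 0.23, tissues = pgx_tissues(),
                           seed = 1, dir = NULL) {
  stopifnot(match_fraction >= 0, match_fraction <= 1)
  set.seed(seed)
  # source intervals from planted panel SVs: their intervals (and ids) are
  # stable through genome-wide clustering, keeping the truth exact
  panel_ids <- cohort$truth$sv_id[cohort$truth$in_panel]
  svs <- as_tibble(cohort$svs) |>
    filter(.data$sv_id %in% panel_ids,
           .data$sv_type %in% c("DEL", "DUP", "INS", "INV"))
  src <- svs[sample(nrow(svs), n_eqtls, replace = n_eqtls > nrow(svs)), ]
  matched <- runif(n_eqtls) < match_fraction
  shift <- sample(150:1000, n_eqtls, replace = TRUE)
  gene_of <- cohort$truth$gene_id[match(src$sv_id, cohort$truth$sv_id)]
  sym <- setNames(genome$gene_set$genes$symbol, genome$gene_set$genes$gene_id)
  eqtls <- tibble(
    chrom = src$chrom,
    start = ifelse(matched, src$start, src$start + shift),
    end = ifelse(matched, src$end, src$end + shift),
    sv_type = src$sv_type,
    gene = ifelse(is.na(gene_of), sample(sym, n_eqtls, replace = TRUE),
                  unname(sym[gene_of])),
    tissue = sample(tissues, n_eqtls, replace = TRUE),
    beta = round(rnorm(n_eqtls, 0, 0.6), 3),
    bh_p = signif(10^(-runif(n_eqtls, 1.5, 20)), 4)
  )
  eqtls$neglog10_bh <- -log10(eqtls$bh_p)
  eqtls$eqtl_id <- paste0("eqtl_", seq_len(n_eqtls))
  truth <- tibble(eqtl_id = eqtls$eqtl_id,
                  sv_id = ifelse(matched, src$sv_id, NA_character_))
  out <- list(eqtls = eqtls, truth = truth)
  if (!is.null(dir)) {
    out$eqtl_path <- file.path(dir, "eqtls.tsv")
    readr::write_tsv(select(eqtls, "chrom", "start", "end", "sv_type",
                            "gene", "tissue", "beta", "bh_p"), out$eqtl_path)
  }
  out
}
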