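# pgxsv

Structural variants (SVs) — deletions, duplications, insertions, inversions,
multi-allelic copy-number variants (MCNVs) and complex rearrangements larger
than 50 bp — are an underappreciated source of variable drug response. `pgxsv`
is an R package for profiling cohort-level structural variation across a
pharmacogene panel (ADME genes and drug targets): it classifies coding SVs
into loss of function (LOF) and increased gene dosage (IGD), screens
non-coding SVs against transcription-factor binding-site (TFBS) clusters with
a tissue co-expression filter, computes per-individual burdens and
Hardy–Weinberg carrier frequencies, cross-references external SV-eQTL
catalogs, and estimates the share of genetically encoded pharmacogenomic
variability carried by non-coding SVs. It is written for pharmacogenomics and
population-genetics analysts working from public cohort summaries (gnomAD-SV
style frequency tables, ENCODE-style TFBS clusters, GTEx-style median
expression), not from raw sequencing data.

## The core quantities

**Functional classification.** An SV is *coding* when it intersects at least
one exon of an assigned gene. Coding deletions, exonic insertions, inversions
with a breakpoint inside the gene span, and partial duplications whose
affected coding bases are not a multiple of 3 are LOF; duplications
containing the whole gene span are IGD. MCNV loci are decomposed around the
reference copy state into deletion-like and duplication-like allele
frequencies and each component is classified separately.

**Burden.** The expected per-individual burden of a set of functional SVs is
the diploid allele dosage

    burden = Σ_sv 2 · AF_sv

grouped by gene class and functional class.

**Carrier frequency.** At an independent locus under Hardy–Weinberg
equilibrium, the carrier fraction is `1 − (1 − AF)²`; the package simulates
100,000 diploid individuals and reports `"1 in N"` with
`N = round(1/fraction)`.

**Non-coding attribution.** With `n_ncSV` functional non-coding SVs,
`n_cSV` functional coding SVs and `n_SNV` functional SNVs per individual
(the SNV count is a literature constant, default 40.6 + 26),

    func_ncSV = n_ncSV / (n_ncSV + n_SNV + n_cSV)

## Worked example

All inputs can be generated synthetically with planted ground truth, so the
full pipeline runs without downloads:

```r
library(pgxsv)

dir <- tempdir()
g   <- generate_genome(n_genes = 50, seed = 7, dir = dir)
co  <- generate_sv_cohort(g, n_svs = 300, seed = 7, dir = dir)
reg <- generate_regulatory_layers(g, co, seed = 7, dir = dir)
eq  <- generate_eqtls(g, co, seed = 7, dir = dir)

cfg <- pgx_config(gene_annotation = g$gtf_path, panel = g$panel_path,
                  sv_table = co$sv_path, tfbs = reg$peaks_path,
                  expression = reg$expr_path, eqtl = eq$eqtl_path, seed = 1)
run <- run_pipeline(cfg)

run$summary$partition
#> # A tibble: 1 × 7
#>   n_total n_coding n_noncoding coding_pct coding_pct_headline n_tfbs tfbs_pct
#>     <int>    <int>       <int>      <dbl>               <dbl>  <int>    <dbl>
#> 1     101       71          30       70.3                  70     10     33.3

run$burden
#> <burden_report> metric = dosage | skipped (no frequency): 0
#> # A tibble: 4 × 5
#>   population group       functional_class burden  n_sv
#>   <chr>      <chr>       <chr>             <dbl> <int>
#> 1 global     ADME        IGD              0.210      7
#> 2 global     ADME        LOF              0.984     21
#> 3 global     drug_target IGD              0.0973     6
#> 4 global     drug_target LOF              0.888     22
```

Of the 101 SVs that reach the gene panel, 71 hit exons (the synthetic quotas
deliberately over-sample coding events; real cohorts are ~15% coding), 30 are
non-coding and 10 of those carry a co-expressed TFBS hit. The burden table
reads: an average individual carries ~0.98 LOF allele dosages in ADME genes
from this cohort. Carrier arithmetic and attribution on published numbers:

```r
sim <- simulate_cohort(tibble::tibble(sv_id = "SULT2A1_DUP", af = 0.054),
                       n = 100000, seed = 1)
carrier_ratio(sim$carrier_fraction)
#> [1] "1 in 10"

percent_of(attribute_variability(n_ncsv = 21.7, n_csv = 10.3 + 1.5),
           headline = TRUE)
#> [1] 22
```

A per-individual load of 21.7 functional non-coding SVs against 11.8 coding
SVs and 66.6 functional SNVs attributes 22% of pharmacogenomic variability to
non-coding structural variation.

## Package layout

- `R/genome_model.R` — GTF/BED12 + panel ingestion, interval queries
- `R/sv_ingest.R` — SV table parsing (TSV/VCF), record filters, MCNV decomposition
- `R/sv_cluster.R` — merge of overlapping/bookended intervals
- `R/annotate.R` — gene assignment, LOF/IGD classification, per-kb densities
- `R/regulatory.R` — TFBS filtering/overlap, tissue co-expression
- `R/burden.R` — dosage burdens, HWE cohort simulation, carrier ratios
- `R/eqtl_xref.R` — SV-eQTL breakpoint/overlap matching and reporting
- `R/attribution.R` — non-coding variability attribution
- `R/synthetic_data.R` — ground-truth generators for every input
- `R/pipeline.R` — configuration, orchestration, summary bookkeeping

See `vignettes/pgxsv-methods.Rmd` for the model, its assumptions, parameter
semantics and design rationale.
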