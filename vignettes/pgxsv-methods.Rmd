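---
title: "Classifying coding and non-coding structural variants in pharmacogenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying coding and non-coding structural variants in pharmacogenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxsv)
library(dplyr)
```

## The problem

Genes encoding drug-metabolizing enzymes and transporters (ADME genes:
cytochrome P450s, phase I/II enzymes, SLC and ABC transporters, nuclear
receptors) and genes encoding drug targets (ion channels, membrane receptors,
enzymes, transporters) carry structural variants — deletions, duplications,
insertions, inversions, multi-allelic copy-number variants (MCNVs) and complex
rearrangements larger than 50 bp. Coding SVs can abolish or multiply a gene
product; non-coding SVs can remove or duplicate transcription-factor binding
sites (TFBS) and thereby shift expression in the tissues where both the gene
and the factor are active. `pgxsv` implements this analysis as a reusable
pipeline over cohort-level SV summaries (gnomAD-SV-style frequencies, not
per-sample genotypes).

## Pipeline and model

1. **Ingest and filter** (`read_sv_table()`, `filter_sv_records()`). Records
   are kept when their filter status is `PASS` or `MULTIALLELIC` and their
   type is neither an unresolved non-reference breakpoint junction nor a
   reciprocal translocation. Every removal is tallied by reason, so
   input = retained + removed holds at each stage.
2. **Merge** (`cluster_sv_table()`). Within each (chromosome, SV type)
   stratum, overlapping and directly adjacent intervals are merged
   (`max_dist = 0`; in half-open coordinates "adjacent" means
   `end1 == start2`). Merging runs genome-wide first and the gene-panel
   restriction happens afterwards, so SVs shared between genes are not
   fragmented. The representative frequency of a cluster is the maximum
   member frequency, which avoids double-counting overlapping call
   fragments of the same event; `freq = "sum"` is available when members
   are known to be distinct alleles.
3. **Assign and classify** (`annotate_svs()`). Each SV joins every gene whose
   span it intersects (multi-gene SVs count once per gene). An SV is *coding*
   when it intersects at least one exon; insertions are represented as 1-bp
   intervals at the insertion point, so the same intersection rule applies.
   Functional classes:
   - deletion over ≥1 exon → **LOF**;
   - insertion inside an exon → **LOF**;
   - inversion with ≥1 breakpoint inside the gene span covering ≥1 exon →
     **LOF**; an inversion containing the entire gene with both breakpoints
     outside leaves the transcription unit intact and is **UNKNOWN**;
   - duplication containing the whole gene span → **IGD** (increased gene
     dosage); a partial duplication over coding exons is **LOF** when the
     summed affected coding bases are not a multiple of 3 (frameshift under
     the tandem in-place assumption), otherwise **UNKNOWN**;
   - complex rearrangements over exons → **UNKNOWN**;
   - non-coding SVs → **NONE** at this stage.
   MCNVs are decomposed around the reference copy state (default 2): mass
   below it is a deletion-like allele frequency, mass above a
   duplication-like one; each non-zero component is classified under the
   DEL/DUP rules, so one locus can legitimately appear as both a common LOF
   deletion and an IGD duplication.
4. **Non-coding screen** (`filter_tfbs()`, `overlap_tfbs()`,
   `coexpression_filter()`). TFBS cluster peaks with score < 200 or support
   from fewer than 2 studies are discarded. A non-coding SV that intersects a
   retained peak forms an (SV, gene, TF) candidate; it becomes a regulatory
   hit when gene and TF are co-expressed (median expression at or above the
   threshold) in at least one tissue of the panel.
5. **Burdens and carriers** (`expected_burden()`, `simulate_cohort()`,
   `carrier_ratio()`). The per-individual burden of a set of functional SVs
   is the expected diploid allele dosage `sum(2 * AF)`. Carrier frequencies
   come from simulating diploid individuals at independent loci under
   Hardy–Weinberg equilibrium and are rendered as "1 in N" with
   `N = round(1 / fraction)` (fractions ≥ 0.75 print as "1 per individual").
6. **eQTL cross-reference** (`match_eqtl()`, `eqtl_report()`). Externally
   estimated SV-eQTLs are matched to cohort SVs by breakpoint proximity
   (both offsets ≤ 100 bp for "near") and by reciprocal overlap (> 99% of
   *both* intervals for inclusion). The two criteria are reported separately.
7. **Attribution** (`attribute_variability()`). The share of genetically
   encoded pharmacogenomic variability carried by non-coding SVs is
   `n_ncSV / (n_ncSV + n_SNV + n_cSV)`, with the per-individual functional
   SNV count supplied as a literature constant (defaults 40.6 for ADME genes
   and 26 for drug targets), never computed here.

```{r example}
f <- attribute_variability(n_ncsv = 21.7, n_csv = 10.3 + 1.5,
                           n_snv = 40.6 + 26)
percent_of(f, headline = TRUE)

sim <- simulate_cohort(tibble::tibble(sv_id = "SULT2A1_DUP", af = 0.054),
                       n = 100000, seed = 1)
carrier_ratio(sim$carrier_fraction)
```

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `max_dist` | 0 bp | merge gap: 0 merges overlapping and bookended intervals |
| `maf_common` | 0.01 | common/rare boundary on the reported SV frequency |
| `min_score` | 200 | minimum TFBS cluster peak score (inclusive) |
| `min_studies` | 2 | minimum studies observing a peak (excludes 1/N peaks) |
| `expr_threshold` | 1 | median expression counted as "expressed" |
| `tissues` | `pgx_tissues()` | 9 tissues of pharmacokinetic/-dynamic relevance |
| `near_bp` | 100 | breakpoint-proximity window for eQTL matching |
| `min_overlap` | 0.99 | reciprocal overlap an included eQTL match must exceed |
| `n` (simulation) | 100,000 | simulated diploid individuals |
| `flank` | 0 bp | span extension for SV-to-gene assignment |

Rarity uses the reported alternate-allele SV frequency directly rather than a
folded minor allele frequency: cohort tables report deletion frequencies of
84.5% as such, and folding them would misstate the biology of a
nearly-fixed deletion. The expression threshold quantifies "expressed", which
the underlying resources leave qualitative; median TPM ≥ 1 is the
conventional floor for calling a gene expressed in bulk tissue.

## Design choices where the design was open

- **Whole-gene inversions.** The LOF rule names exon-spanning inversions; an
  inversion whose breakpoints both lie outside the gene moves the gene as a
  unit without truncating it, so it is classified UNKNOWN rather than LOF.
  Flagged for sensitivity analysis.
- **Frameshift test for partial duplications.** The criterion is a
  frameshift, but the computation is unstated; we assume a tandem in-place
  duplication so the duplicated coding length equals the overlap with coding
  exons, and test it modulo 3. With CDS annotation available, UTR-only
  overlaps are UNKNOWN and frame arithmetic uses CDS bases only.
- **Burden metric.** Per-individual figures are expected allele dosages
  (`sum(2 * AF)`), not carrier probabilities: a single deletion at 84.5%
  frequency then contributes 1.69 SVs per individual, which is the scale the
  headline per-individual numbers live on. `metric = "carrier"` switches to
  `sum(1 - (1 - AF)^2)`.
- **TFBS evaluation window.** A peak counts when it overlaps the SV anywhere
  (`region = "sv"`), matching the plain reading of "SV overlapped a TFBS".
  Because very large SVs can extend far beyond the gene they are assigned
  to, `region = "gene_flank"` restricts the window to the SV's intersection
  with the gene span plus a flank.
- **Reciprocal eQTL overlap.** One-sided overlap would let a 100-bp SV
  "match" a 100-kb eQTL interval that merely contains it; inclusion therefore
  requires > `min_overlap` of both intervals. Insertions, having no length on
  the reference, match by insertion-point distance and take overlap 1 when
  within `near_bp`.
- **MCNV population split.** Population-stratified tables carry one frequency
  per locus; deletion- and duplication-like components split it
  proportionally to their global shares, assuming the component balance is
  population-invariant.
- **Gene span and length.** The span is the exon hull of the canonical
  (longest) transcript (`transcript = "union"` merges all transcripts), and
  per-kb densities use this span length; annotation sources differ in how
  they define gene-body length, so the choice is explicit and configurable
  via `flank`.
- **Multiple testing.** Density comparisons report raw two-sided Wilcoxon
  rank-sum p-values at α = 0.05; a Benjamini–Hochberg option exists but is
  off by default, matching the reporting convention the pipeline mirrors.

## What the synthetic generator emulates — and what it does not

`generate_genome()`, `generate_sv_cohort()`, `generate_regulatory_layers()`
and `generate_eqtls()` produce every input the pipeline reads, with planted
ground truth: gene structures with panel classes, SVs of every type with
known gene assignment/coding status/functional class, allele frequencies from
a rare-heavy Beta(0.2, 20) mixed with common point masses (both rarity strata
are always populated), TFBS peaks straddling the score-200 and 2-study
boundaries, an expression matrix realizing planted co-expression triples
exactly at the threshold, and eQTLs with a controlled matched share.

Two generator properties keep the truth exact end-to-end: filler SVs are
placed intergenically with margins, and planted SVs of mergeable types (DUP,
INV, MCNV) go to distinct genes, so genome-wide clustering never merges a
planted event into something with a different truth label. Consequently the
generator does *not* emulate: fragmented call sets where one biological event
appears as several overlapping records inside a gene, linkage between loci,
realistic genome sequence, multi-chromosome layouts, or SVs spanning several
genes. Passing the recovery tests therefore demonstrates correctness of the
classification and filtering logic under clean conditions, not robustness to
caller artifacts in real cohort data.

Default problem sizes in the test-suite runs are 40–50 genes, 300–500 SV
records and 100,000 simulated individuals; generation and a full pipeline run
complete in a few seconds.

## Numerical notes and degenerate inputs

- Coordinates are 0-based half-open everywhere internally; GTF is converted
  on read, BED is native. Interval clustering sorts by (start, end, id), so
  results are independent of input order.
- MCNV spectra must sum to ≤ 1; a spectrum entirely at the reference copy
  state yields no component rows (there is no variant allele) and is counted
  in the annotation log.
- Records lacking a population's frequency are skipped in that population's
  burden (with a logged count) rather than imputed as zero; absent
  frequencies on ingest stay `NA`.
- `carrier_ratio(0)` returns `"0"`; the "1 per individual" cut at 0.75
  prevents reporting "1 in 1" for fractions that round to unity.
- Carrier ratios are reported as `round(1/fraction)`; when the true
  reciprocal lies close to a half-integer (e.g. 1/0.1051 ≈ 9.5), single
  simulation draws at n = 100,000 can land on either side of the rounding
  boundary. The closed form `1 − (1 − AF)²` is the stable reference the
  property tests converge to.
- Empty comparison classes in `density_table()` skip the test with a warning
  instead of erroring, so a panel without, say, olfactory genes still
  produces the remaining comparisons.

## Limitations

Only cohort summary frequencies are modeled — no per-sample genotypes, no
linkage, no haplotype phasing; the simulation treats loci as independent.
Functional classes are rule-based predictions, not experimentally validated
consequences; direction of regulatory effects is reported as a hint
(ablation/gain/disruption/complex) and no quantitative expression change is
predicted. Star-allele nomenclature, transcript-resolution consequence
prediction and eQTL estimation from raw genotype × expression data are out of
scope.
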