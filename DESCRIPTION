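Package: pgxsv
Title: Structural Variant Analysis of the Coding and Non-Coding Pharmacogenome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to profile structural variation (deletions, duplications,
    insertions, inversions, multi-allelic copy-number variants and complex
    rearrangements) across pharmacogenes. Ingests cohort-level SV tables
    (VCF or TSV) with population-stratified allele frequencies, merges
    overlapping and bookended intervals, assigns SVs to genes from GTF/BED12
    annotation, classifies coding consequences (loss of function, increased
    gene dosage), infers putative functionality of non-coding SVs from
    transcription-factor binding-site overlap combined with TF-gene tissue
    co-expression, computes per-individual burdens and Hardy-Weinberg
    carrier-frequency simulations, cross-references SV-eQTL catalogs by
    breakpoint proximity and reciprocal overlap, and estimates the share of
    genetically encoded pharmacogenomic variability attributable to
    non-coding structural variants. Includes a synthetic-data generator
    that emulates every input with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stringr,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
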