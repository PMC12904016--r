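Package: ncsvtools
Title: Prioritization and Protein-Level Consequence Analysis of Non-Canonical
    Splicing Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for non-canonical splicing variant (NCSV)
    analysis: dual-threshold prioritization of potential splice-altering
    variants from annotated variant tables (SPCards-style supporting-method
    counts and SpliceAI scores), genomic/cDNA (HGVS-c) coordinate mapping on
    multi-exon transcript models, application of aberrant splicing events
    (exon skipping, partial exon deletion, intron retention) to derive
    HGVS-p protein consequences and the disrupted-protein fraction, ClinGen
    PVS1_Strong strength assignment under the greater-than-10-percent rule,
    biallelic/X-linked inheritance screening of exome cohorts, catalog
    summary statistics (consensus-region share, Fisher's exact test, score
    correlation), and a seeded synthetic-data generator that produces toy
    genomes, transcripts, variant catalogs, spiked splice events with known
    protein truth, and cohort genotype tables so that every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    rtracklayer,
    GenomicRanges,
    IRanges,
    vcfR,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
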