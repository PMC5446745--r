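Package: transpopgen
Title: Population Divergence and Diversity from Transcriptome SNPs
Version: 1.0.0
Authors@R: person("transpopgen", "developers", email = "maintainer@transpopgen.dev", role = c("aut", "cre"))
Description: An end-to-end pipeline for two-population divergence analysis of
    biallelic SNPs called on assembled transcripts (unigenes): GATK-style
    hard-filter cascade with per-rule accounting, per-SNP differentiation
    statistics (Nei's G_ST with and without Nei-Chesser small-sample
    correction, Hedrick's G'_ST, Jost's D, AMOVA-based phi_ST) with Fisher
    exact-test significance under Bonferroni correction, per-unigene
    nucleotide diversity and Tajima's D with percentile outlier calling,
    synonymous/nonsynonymous/UTR/noncoding SNP effect classification against
    transcript ORFs, complete-case genotype PCA with k-means cluster
    summaries, and a Balding-Nichols synthetic-data generator that emulates a
    derived population drawn from one subcluster of ancestral standing
    variation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    optparse,
    Biostrings,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
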