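Package: cfsomatic
Title: Somatic Mutation Post-Processing and Clinical Association for Plasma cfDNA Exomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for post-processing somatic mutation calls from plasma
    cell-free DNA (cfDNA) tumor/normal whole-exome sequencing and relating
    them to clinical outcome. Reads the VCF dialects of five somatic callers
    (MuSE, Mutect2, Strelka2, SomaticSniper, VarDict), merges them into a
    union consensus keyed by sample and allele, applies a six-rule somatic
    filter cascade (population allele frequency, panel of normals,
    8-oxoguanine orientation artifacts, multiallelic/clustered/strand-bias
    sites, mutant allele support, variant allele frequency) plus a recurrent
    false-positive gene blacklist, automates IGV-style read-level validation
    from pileup windows, annotates variant consequences against a minimal
    gene model, computes plasma mutation burden (PMB, mutations per megabase
    at VAF >= 5%), and runs the clinical association battery (Mann-Whitney,
    Spearman, chi-square/Fisher, age-adjusted regression, Kaplan-Meier with
    log-rank, Bonferroni correction, power analysis). A seeded synthetic
    cohort generator emits caller VCFs, pileups, gene models and clinical
    tables with a ground-truth manifest so the whole pipeline is testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    vcfR,
    IRanges,
    Biostrings,
    survival,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
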