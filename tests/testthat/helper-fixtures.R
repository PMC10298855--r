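# Shared fixtures: tiny variant tables, a small simulated cohort, and the
# published 25-gene IGV validation counts.

caller_variant_row <- function(caller = "mutect2", sample_id = "S1",
                               chrom = "chr1", pos = 100L, ref = "A",
                               alt = "T", tumor_depth = 80L,
                               tumor_alt = 20L, normal_depth = 80L,
                               normal_alt = 0L, alt_fwd = 10L,
                               alt_rev = 10L, ref_fwd = 30L, ref_rev = 30L,
                               f1r2 = 10L, f2r1 = 10L,
                               multiallelic = FALSE,
                               strand_unknown = FALSE, gene = NA_character_) {
  tibble::tibble(
    caller = caller, sample_id = sample_id, chrom = chrom, pos = pos,
    ref = ref, alt = alt, tumor_depth = tumor_depth, tumor_alt = tumor_alt,
    normal_depth = normal_depth, normal_alt = normal_alt,
    alt_fwd = alt_fwd, alt_rev = alt_rev, ref_fwd = ref_fwd,
    ref_rev = ref_rev, f1r2 = f1r2, f2r1 = f2r1,
    multiallelic = multiallelic, strand_unknown = strand_unknown,
    vaf = ifelse(tumor_depth > 0, tumor_alt / tumor_depth, NA_real_),
    gene = gene
  )
}

merged_row <- function(...) {
  v <- caller_variant_row(...)
  v$key <- variant_key(v$sample_id, v$chrom, v$pos, v$ref, v$alt)
  v$callers <- v$caller
  v$n_callers <- 1L
  v$caller <- NULL
  v
}

# one small end-to-end cohort, shared across test files (composition
# matches the full-size study per Mb; see sim_config_scaled)
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config_scaled(seed = 42L, n_patients = 10L, target_mb = 4)
      cache <<- simulate_cohort(cfg)
    }
    cache
  }
})

# cohort with abundant artifacts for classifier checks (per-class rates
# are class-conditional, so abundance does not distort them)
artifact_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        seed = 99L, n_patients = 6L, target_mb = 2,
        germline_snps = 15L,
        artifacts_per_patient = c(oxog = 20L, strand_bias = 20L,
                                  cluster_mismatch = 20L,
                                  low_support = 20L, blacklist_fp = 4L),
        n_position_clusters = 3L, n_pon_sites = 12L,
        caller_fp_per_patient = c(muse = 4L, mutect2 = 2L, strelka2 = 6L,
                                  somaticsniper = 3L, vardict = 5L),
        n_filler_genes = 20L, cds_codons = 2000L
      )
      cache <<- simulate_cohort(cfg)
    }
    cache
  }
})

published_igv_counts <- function() {
  readr::read_tsv(
    system.file("extdata", "igv_validation_counts.tsv",
                package = "cfsomatic"),
    show_col_types = FALSE
  )
}

run_scaled_pipeline <- function(cohort, config = filter_config()) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  emit_caller_vcfs(cohort, dir)
  calls <- suppressMessages(read_caller_vcf_dir(dir))
  calls <- normalize_variants(calls, cohort$genome$reference)
  merged <- merge_callers(calls)
  merged <- assign_genes(merged, cohort$genome$models)
  cascade <- apply_cascade(merged, config, af_lookup = cohort$af_table,
                           pon_sites = cohort$pon_sites)
  list(merged = merged, cascade = cascade)
}

# all permutations of 1..n (for exhaustive rank-statistic oracles)
combinat_permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- combinat_permutations(n - 1)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  r <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[r, ] <- c(k, rest[sub[i, ]])
      r <- r + 1L
    }
  }
  out
}
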