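#' Run the somatic post-processing pipeline end to end
#'
#' Reads per-caller VCFs from a directory, normalizes and merges them,
#' assigns genes, applies the filter cascade, annotates consequences of
#' the kept variants and computes per-patient burden. This is the
#' file-level composition of the individual steps; each step remains
#' available on its own.
#'
#' @param vcf_dir Directory of `<sample>.<caller>.vcf` files.
#' @param reference Named character vector of chromosome sequences (or
#'   `NULL` to skip indel left-alignment and reference checks).
#' @param models Gene model tibble.
#' @param targets `cf_targets` object (defaults to the universal 91.08 Mb
#'   target).
#' @param af_lookup,pon_sites Population AF table and PoN locus keys for
#'   the cascade.
#' @param config A [filter_config()].
#' @param patients Optional full patient list for the burden table.
#' @param pmb_min_vaf Qualifying VAF for the burden statistic (0.05 by
#'   definition, independent of the cascade's `min_vaf` profile).
#' @return List: `merged`, `cascade` (`cf_cascade`), `kept` (annotated),
#'   `burden`.
#' @export
somatic_pipeline <- function(vcf_dir, reference = NULL, models = NULL,
                             targets = read_target_regions(),
                             af_lookup = NULL, pon_sites = NULL,
                             config = filter_config(), patients = NULL,
                             pmb_min_vaf = 0.05) {
  calls <- read_caller_vcf_dir(vcf_dir)
  calls <- normalize_variants(calls, reference)
  merged <- merge_callers(calls)
  if (!is.null(models)) merged <- assign_genes(merged, models)
  cascade <- apply_cascade(merged, config, af_lookup = af_lookup,
                           pon_sites = pon_sites)
  kept <- cascade$kept
  if (!is.null(models) && !is.null(reference) && nrow(kept) > 0) {
    kept <- classify_consequences(kept, models, reference)
  }
  burden <- compute_pmb(kept, targets, min_vaf = pmb_min_vaf,
                        patients = patients %||%
                          sort(unique(merged$sample_id)))
  list(merged = merged, cascade = cascade, kept = kept, burden = burden)
}
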