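#' Somatic filter configuration
#'
#' Thresholds for the six-rule somatic filter cascade plus the recurrent
#' false-positive gene blacklist. Defaults follow the study rules: drop
#' variants with population minor allele frequency > 1%, panel-of-normals
#' hits, 8-oxoguanine orientation artifacts, multiallelic/clustered/
#' strand-biased sites, tumor alt reads < 4 or normal alt reads >= 4, VAF
#' < 5%, and any mutation in MUC16/MUC19. A `min_vaf = 0.02` profile is
#' supported for assays read down to the ~2% detection limit.
#'
#' @param max_population_af Population MAF above which a variant is a
#'   common polymorphism (strict inequality; default 0.01).
#' @param min_tumor_alt Minimum alt-supporting reads in cfDNA (default 4).
#' @param max_normal_alt Normal-sample alt reads at or above which the
#'   variant is dropped (default 4).
#' @param min_vaf Minimum cfDNA variant allele frequency (default 0.05;
#'   values at the threshold are kept).
#' @param clustered_window_bp,clustered_min_events A variant is clustered
#'   when some window of `clustered_window_bp` bases holds at least
#'   `clustered_min_events` same-sample variants (defaults 100 bp, 3).
#' @param strand_bias_p One-sided exact-test p-value below which alt-strand
#'   imbalance is called (default 0.005).
#' @param oxog_min_ratio Minimum fraction of alt-supporting read pairs in
#'   one orientation (F1R2 vs F2R1) for a C>A/G>T call to be flagged as an
#'   8-oxoguanine artifact (default 0.9, requiring >= 3 informative pairs).
#' @param blacklist_genes Gene symbols removed outright (default MUC16,
#'   MUC19).
#' @return A `cf_filter_config` list.
#' @export
filter_config <- function(max_population_af = 0.01,
                          min_tumor_alt = 4L,
                          max_normal_alt = 4L,
                          min_vaf = 0.05,
                          clustered_window_bp = 100L,
                          clustered_min_events = 3L,
                          strand_bias_p = 0.005,
                          oxog_min_ratio = 0.9,
                          blacklist_genes = c("MUC16", "MUC19")) {
  stopifnot(max_population_af >= 0, max_population_af <= 1,
            min_tumor_alt >= 0, max_normal_alt >= 0,
            min_vaf >= 0, min_vaf <= 1,
            clustered_window_bp >= 1, clustered_min_events >= 1,
            strand_bias_p > 0, strand_bias_p < 1,
            oxog_min_ratio > 0.5, oxog_min_ratio <= 1)
  structure(
    list(max_population_af = max_population_af,
         min_tumor_alt = as.integer(min_tumor_alt),
         max_normal_alt = as.integer(max_normal_alt),
         min_vaf = min_vaf,
         clustered_window_bp = as.integer(clustered_window_bp),
         clustered_min_events = as.integer(clustered_min_events),
         strand_bias_p = strand_bias_p,
         oxog_min_ratio = oxog_min_ratio,
         blacklist_genes = blacklist_genes),
    class = "cf_filter_config"
  )
}

#' Individual somatic filters
#'
#' Each filter is a vectorized predicate over a merged variant table,
#' returning `TRUE` where the filter fires (variant removed). They are
#' exposed individually for auditing; [apply_cascade()] runs all of them
#' and records the full trace.
#'
#' @param variants Merged variant tibble ([merge_callers()] output).
#' @param af_lookup Tibble with columns `chrom`, `pos`, `ref`, `alt`, `af`
#'   (population minor allele frequency); absent alleles count as AF 0.
#' @param pon_sites Character vector of panel-of-normals locus keys
#'   (`chrom-pos-ref-alt`, see [locus_key()]).
#' @param config A [filter_config()].
#' @return Logical vector (or, for [filter_site_artifacts()], a tibble of
#'   the three sub-flags `multiallelic`, `clustered`, `strand_bias`).
#' @name somatic_filters
NULL

#' @rdname somatic_filters
#' @export
filter_population_af <- function(variants, af_lookup,
                                 config = filter_config()) {
  if (is.null(af_lookup) || nrow(af_lookup) == 0) {
    return(rep(FALSE, nrow(variants)))
  }
  lk <- locus_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  af <- af_lookup$af[match(lk, locus_key(af_lookup$chrom, af_lookup$pos,
                                         af_lookup$ref, af_lookup$alt))]
  af[is.na(af)] <- 0
  af > config$max_population_af
}

#' @rdname somatic_filters
#' @export
filter_panel_of_normals <- function(variants, pon_sites,
                                    config = filter_config()) {
  if (is.null(pon_sites) || length(pon_sites) == 0) {
    return(rep(FALSE, nrow(variants)))
  }
  lk <- locus_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  lk %in% pon_sites
}

#' @rdname somatic_filters
#' @export
filter_oxog <- function(variants, config = filter_config()) {
  sub_type <- paste0(variants$ref, ">", variants$alt)
  is_oxo_class <- sub_type %in% c("C>A", "G>T")
  n_orient <- variants$f1r2 + variants$f2r1
  ratio <- pmax(variants$f1r2, variants$f2r1) / n_orient
  fired <- is_oxo_class & !is.na(n_orient) & n_orient >= 3 &
    ratio >= config$oxog_min_ratio
  fired[is.na(fired)] <- FALSE
  fired
}

#' @rdname somatic_filters
#' @export
filter_site_artifacts <- function(variants, config = filter_config()) {
  n <- nrow(variants)
  # (a) multiallelic: flagged by the caller, or >1 alt allele at the site
  n_alleles <- variants |>
    mutate(.row = row_number()) |>
    group_by(sample_id, chrom, pos) |>
    mutate(.n_alt = n_distinct(alt)) |>
    ungroup()
  multi <- (variants$multiallelic %||% rep(FALSE, n)) | n_alleles$.n_alt > 1
  multi[is.na(multi)] <- FALSE

  # (b) clustered events: >= k same-sample variants in some w-bp window
  clustered <- rep(FALSE, n)
  idx <- split(seq_len(n), paste(variants$sample_id, variants$chrom))
  w <- config$clustered_window_bp
  k <- config$clustered_min_events
  for (sel in idx) {
    p <- variants$pos[sel]
    o <- order(p)
    ps <- p[o]
    m <- length(ps)
    if (m < k) next
    in_run <- rep(FALSE, m)
    for (i in seq_len(m - k + 1)) {
      if (ps[i + k - 1] - ps[i] < w) in_run[i:(i + k - 1)] <- TRUE
    }
    clustered[sel[o]] <- in_run
  }

  # (c) strand bias: one-sided exact (hypergeometric-tail) test on the
  # ref/alt x fwd/rev table; ref strand counts assumed balanced when the
  # caller does not report them; strand-unknown evidence is exempt
  af <- variants$alt_fwd
  ar <- variants$alt_rev
  ref_n <- pmax(variants$tumor_depth - variants$tumor_alt, 0L)
  rf <- variants$ref_fwd
  rr <- variants$ref_rev
  assume <- is.na(rf) | is.na(rr)
  rf[assume] <- floor(ref_n[assume] / 2)
  rr[assume] <- ref_n[assume] - rf[assume]
  p_sb <- strand_bias_p_value(rf, rr, af, ar)
  strand_bias <- !is.na(p_sb) & p_sb < config$strand_bias_p
  strand_bias[variants$strand_unknown %||% rep(FALSE, n)] <- FALSE

  tibble(multiallelic = multi, clustered = clustered,
         strand_bias = strand_bias)
}

#' One-sided strand-bias p-value
#'
#' Exact one-sided test of alt-strand imbalance on the 2x2 table
#' (ref/alt x fwd/rev): the smaller of the two hypergeometric tail
#' probabilities of the observed alt-forward count, i.e. a one-sided
#' Fisher test in the direction of the observed imbalance.
#'
#' @param ref_fwd,ref_rev,alt_fwd,alt_rev Integer vectors of read counts.
#' @return Numeric vector of p-values (`NA` where counts are missing).
#' @export
strand_bias_p_value <- function(ref_fwd, ref_rev, alt_fwd, alt_rev) {
  fwd <- ref_fwd + alt_fwd
  rev <- ref_rev + alt_rev
  k <- alt_fwd + alt_rev
  p_hi <- phyper(alt_fwd - 1, fwd, rev, k, lower.tail = FALSE)
  p_lo <- phyper(alt_fwd, fwd, rev, k, lower.tail = TRUE)
  pmin(p_hi, p_lo)
}

#' @rdname somatic_filters
#' @export
filter_allele_support <- function(variants, config = filter_config()) {
  variants$tumor_alt < config$min_tumor_alt |
    variants$normal_alt >= config$max_normal_alt
}

#' @rdname somatic_filters
#' @export
filter_vaf <- function(variants, config = filter_config()) {
  no_cov <- is.na(variants$vaf) | variants$tumor_depth == 0
  fired <- variants$vaf < config$min_vaf
  fired[no_cov] <- TRUE
  fired
}

#' @rdname somatic_filters
#' @export
filter_blacklist_genes <- function(variants, config = filter_config()) {
  if (!"gene" %in% names(variants)) return(rep(FALSE, nrow(variants)))
  !is.na(variants$gene) & variants$gene %in% config$blacklist_genes
}

#' Apply the full somatic filter cascade
#'
#' Evaluates every filter on every variant — no short-circuiting — so the
#' trace supports per-filter attrition reporting. A variant is kept iff no
#' filter fires. Filters are independent predicates, so the kept set does
#' not depend on evaluation order.
#'
#' @inheritParams somatic_filters
#' @return A `cf_cascade` object: list with `kept` and `dropped` variant
#'   tibbles, and `trace`, a long tibble (`key`, `filter_name`, `fired`).
#'   `tidy()` returns the trace; `glance()` the per-filter attrition.
#' @export
apply_cascade <- function(variants, config = filter_config(),
                          af_lookup = NULL, pon_sites = NULL) {
  variants <- as_tibble(variants)
  site <- filter_site_artifacts(variants, config)
  flags <- tibble(
    population_af = filter_population_af(variants, af_lookup, config),
    panel_of_normals = filter_panel_of_normals(variants, pon_sites, config),
    oxog = filter_oxog(variants, config),
    multiallelic = site$multiallelic,
    clustered = site$clustered,
    strand_bias = site$strand_bias,
    allele_support = filter_allele_support(variants, config),
    vaf = filter_vaf(variants, config),
    blacklist_gene = filter_blacklist_genes(variants, config)
  )
  any_fired <- Reduce(`|`, flags)
  trace <- bind_cols(tibble(key = variants$key), flags) |>
    tidyr::pivot_longer(-key, names_to = "filter_name",
                        values_to = "fired")
  structure(
    list(kept = variants[!any_fired, ],
         dropped = variants[any_fired, ],
         trace = trace,
         config = config,
         flags = bind_cols(tibble(key = variants$key), flags)),
    class = "cf_cascade"
  )
}

#' @exportS3Method base::print
print.cf_cascade <- function(x, ...) {
  cat(sprintf("<cf_cascade> %d input, %d kept, %d dropped\n",
              nrow(x$kept) + nrow(x$dropped), nrow(x$kept),
              nrow(x$dropped)))
  print(glance(x))
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.cf_cascade <- function(x, ...) x$trace

#' @export
#' @importFrom generics glance
glance.cf_cascade <- function(x, ...) {
  attrition <- x$trace |>
    group_by(filter_name) |>
    summarise(n_fired = sum(fired)) |>
    tidyr::pivot_wider(names_from = filter_name, values_from = n_fired,
                       names_prefix = "fired_")
  bind_cols(
    tibble(n_input = nrow(x$kept) + nrow(x$dropped),
           n_kept = nrow(x$kept), n_dropped = nrow(x$dropped)),
    attrition
  )
}
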