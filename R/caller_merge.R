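#' Normalize variant representations to a canonical form
#'
#' Cross-caller merging keys on `sample-chrom-pos-ref-alt`, so every caller's
#' representation of the same allele must be byte-identical first. SNVs are
#' already minimal; indels are trimmed of shared prefix/suffix bases and
#' left-aligned against the reference (the classical parsimony + left-shift
#' normalization), keeping the usual VCF anchor base.
#'
#' @param variants Tibble of caller variants with `chrom`, `pos`, `ref`,
#'   `alt` columns.
#' @param reference Named character vector (or `Biostrings::DNAStringSet`)
#'   of chromosome sequences. Required only when indels are present.
#' @return The input tibble with `pos`, `ref`, `alt` normalized.
#' @export
normalize_variants <- function(variants, reference = NULL) {
  variants <- as_tibble(variants)
  if (nrow(variants) == 0) return(variants)
  if (any(variants$ref == "" | variants$alt == "")) {
    abort("ref and alt must be non-empty")
  }
  refseq <- as_reference(reference)
  needs <- which(nchar(variants$ref) > 1 | nchar(variants$alt) > 1)
  for (i in needs) {
    n <- normalize_one(variants$chrom[i], variants$pos[i],
                       variants$ref[i], variants$alt[i], refseq)
    variants$pos[i] <- n$pos
    variants$ref[i] <- n$ref
    variants$alt[i] <- n$alt
  }
  if (!is.null(refseq)) {
    check_ref_consistency(variants, refseq)
  }
  if ("key" %in% names(variants) || all(c("sample_id") %in% names(variants))) {
    # refresh key if present or derivable
    if ("sample_id" %in% names(variants)) {
      variants$key <- variant_key(variants$sample_id, variants$chrom,
                                  variants$pos, variants$ref, variants$alt)
    }
  }
  variants
}

as_reference <- function(reference) {
  if (is.null(reference)) return(NULL)
  if (inherits(reference, "DNAStringSet")) {
    return(setNames(as.character(reference), names(reference)))
  }
  reference
}

normalize_one <- function(chrom, pos, ref, alt, refseq) {
  # trim shared suffix (keep at least one base each)
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  # trim shared prefix, advancing pos
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  if (nchar(ref) == 1 && nchar(alt) == 1) {
    return(list(pos = pos, ref = ref, alt = alt))
  }
  # indel: truncate equal trailing bases, extending left from the
  # reference whenever an allele would empty (classical left-shift)
  if (!is.null(refseq) && !is.null(refseq[[chrom]])) {
    seq <- refseq[[chrom]]
    repeat {
      if (substr(ref, nchar(ref), nchar(ref)) !=
          substr(alt, nchar(alt), nchar(alt))) break
      ref <- substr(ref, 1, nchar(ref) - 1)
      alt <- substr(alt, 1, nchar(alt) - 1)
      if (nchar(ref) == 0 || nchar(alt) == 0) {
        if (pos <= 1) {
          abort("cannot left-align indel at contig start")
        }
        prev <- substr(seq, pos - 1, pos - 1)
        ref <- paste0(prev, ref)
        alt <- paste0(prev, alt)
        pos <- pos - 1L
      }
    }
    while (nchar(ref) > 1 && nchar(alt) > 1 &&
           substr(ref, 1, 1) == substr(alt, 1, 1)) {
      ref <- substr(ref, 2, nchar(ref))
      alt <- substr(alt, 2, nchar(alt))
      pos <- pos + 1L
    }
  }
  list(pos = pos, ref = ref, alt = alt)
}

check_ref_consistency <- function(variants, refseq) {
  for (cc in intersect(unique(variants$chrom), names(refseq))) {
    sel <- which(variants$chrom == cc)
    obs <- substr(rep(refseq[[cc]], length(sel)), variants$pos[sel],
                  variants$pos[sel] + nchar(variants$ref[sel]) - 1L)
    bad <- sel[obs != variants$ref[sel]]
    if (length(bad)) {
      abort(sprintf(
        "ref allele disagrees with reference at %s:%d (%s vs %s)",
        variants$chrom[bad[1]], variants$pos[bad[1]],
        variants$ref[bad[1]], obs[which(obs != variants$ref[sel])[1]]
      ))
    }
  }
  invisible(variants)
}

#' Merge five caller call sets into consensus records
#'
#' Union merge keyed on `sample-chrom-pos-ref-alt`: a variant called by any
#' caller enters the merged set, and the set of supporting callers is
#' recorded. For downstream counting one "consolidated" evidence record is
#' chosen per key from the highest-priority supporting caller (priority
#' defaults to descending completeness of count/strand/orientation fields).
#' Duplicate reports of one key by one caller raise a warning and keep the
#' first.
#'
#' @param variants Tidy caller-variant tibble (all callers stacked;
#'   see [read_caller_vcf()]).
#' @param priority Character vector ordering callers for consolidation.
#' @param min_callers Minimum number of supporting callers for a merged
#'   record to be retained (1 = union, 5 = strict intersection).
#' @return Tibble with one row per merged variant: key fields, `callers`
#'   (comma-joined, in priority order), `n_callers`, and the consolidated
#'   evidence columns (`tumor_depth` ... `vaf`, `multiallelic`,
#'   `strand_unknown`).
#' @export
merge_callers <- function(variants,
                          priority = c("mutect2", "strelka2", "vardict",
                                       "muse", "somaticsniper"),
                          min_callers = 1L) {
  variants <- as_tibble(variants)
  if (nrow(variants) == 0) {
    out <- empty_caller_variants() |>
      mutate(key = character(), callers = character(),
             n_callers = integer()) |>
      select(-caller)
    return(out)
  }
  variants$key <- variant_key(variants$sample_id, variants$chrom,
                              variants$pos, variants$ref, variants$alt)
  dup <- duplicated(variants[, c("key", "caller")])
  if (any(dup)) {
    warn(sprintf("%d duplicate caller record(s) dropped (first kept)",
                 sum(dup)))
    variants <- variants[!dup, ]
  }
  variants$priority <- match(variants$caller, priority)
  if (anyNA(variants$priority)) {
    abort("caller not listed in priority vector")
  }
  merged <- variants |>
    arrange(key, priority) |>
    group_by(key) |>
    mutate(callers = paste(caller, collapse = ","),
           n_callers = n()) |>
    slice(1) |>
    ungroup() |>
    select(-caller, -priority) |>
    relocate(key, sample_id, chrom, pos, ref, alt, callers, n_callers)
  merged <- merged[merged$n_callers >= min_callers, ]
  arrange(merged, sample_id, chrom, pos, ref, alt)
}

#' Caller support histogram
#'
#' Counts of deduplicated calls per caller and of merged variants per
#' support level (how many callers agreed).
#'
#' @param merged Output of [merge_callers()].
#' @return List with tibbles `by_caller` (`caller`, `n`) and `by_support`
#'   (`n_callers`, `n`).
#' @export
support_histogram <- function(merged) {
  by_caller <- tibble(caller = CALLERS) |>
    left_join(
      merged |>
        tidyr::separate_rows(callers, sep = ",") |>
        count(callers),
      by = c(caller = "callers")
    ) |>
    mutate(n = ifelse(is.na(n), 0L, n))
  by_support <- merged |>
    count(n_callers) |>
    arrange(n_callers)
  list(by_caller = by_caller, by_support = by_support)
}
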