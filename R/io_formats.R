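#' Read one somatic caller's VCF into a normalized variant table
#'
#' Each of the five supported callers writes tumor/normal read support in its
#' own FORMAT dialect. This reader maps every record to a common schema with
#' tumor/normal depths and alt counts, alt-strand counts where the caller
#' reports them, and alt-supporting read-pair orientation (F1R2/F2R1) where
#' available (Mutect2 only). Multi-allelic records are expanded to one row
#' per alternate allele and flagged.
#'
#' Field mapping by dialect:
#' \describe{
#'   \item{mutect2}{`AD` ref/alt counts, `DP` depth, `SB` per-strand
#'     ref/alt counts, `F1R2`/`F2R1` orientation counts.}
#'   \item{strelka2}{tier-1 allele counts from `AU`/`CU`/`GU`/`TU` (SNVs) or
#'     `TAR`/`TIR` (indels), `DP` depth; strand counts are not reported.}
#'   \item{vardict}{`AD`, `DP`, `ALD` (alt fwd/rev), `RD` (ref fwd/rev).}
#'   \item{muse, somaticsniper}{`AD`, `DP` only; strand counts absent.}
#' }
#' Records whose alt count cannot be extracted from any fallback tag are not
#' silently dropped: they are collected in the `"rejected"` attribute of the
#' result (with their record line index) and reported via a message.
#'
#' @param path Path to a VCF file with `TUMOR` and `NORMAL` sample columns.
#' @param caller_name One of `"muse"`, `"mutect2"`, `"strelka2"`,
#'   `"somaticsniper"`, `"vardict"`; selects the field mapping.
#' @param sample_id Sample identifier to attach; defaults to the file name
#'   stripped of caller/extension suffixes.
#' @return A tibble with one row per allele: `caller`, `sample_id`, `chrom`,
#'   `pos` (1-based), `ref`, `alt`, `tumor_depth`, `tumor_alt`,
#'   `normal_depth`, `normal_alt`, `alt_fwd`, `alt_rev`, `ref_fwd`,
#'   `ref_rev`, `f1r2`, `f2r1`, `vaf`, `multiallelic`, `strand_unknown`.
#' @export
read_caller_vcf <- function(path, caller_name, sample_id = NULL) {
  caller_name <- match.arg(caller_name, CALLERS)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(vcf|vcf\\.gz)$", "", basename(path))
    sample_id <- sub(paste0("[._]", caller_name, "$"), "", sample_id)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (nrow(fix) == 0) {
    return(empty_caller_variants())
  }
  gt <- vcf@gt
  samp <- colnames(gt)[-1]
  tumor_col <- samp[toupper(samp) == "TUMOR"]
  normal_col <- samp[toupper(samp) == "NORMAL"]
  if (length(tumor_col) != 1 || length(normal_col) != 1) {
    abort(sprintf(
      "VCF '%s' must have TUMOR and NORMAL sample columns (found: %s)",
      path, paste(samp, collapse = ", ")
    ))
  }

  tag <- function(el) {
    m <- tryCatch(
      vcfR::extract.gt(vcf, element = el),
      error = function(e) NULL
    )
    if (is.null(m)) {
      return(list(tumor = rep(NA_character_, nrow(fix)),
                  normal = rep(NA_character_, nrow(fix))))
    }
    list(tumor = unname(m[, tumor_col]), normal = unname(m[, normal_col]))
  }
  nth_int <- function(x, i) {
    # i-th comma-separated integer of a tag value (vectorized over x and i)
    out <- mapply(function(s, k) {
      if (is.na(s)) return(NA_integer_)
      parts <- strsplit(s, ",", fixed = TRUE)[[1]]
      if (k > length(parts)) return(NA_integer_)
      suppressWarnings(as.integer(parts[k]))
    }, x, i, USE.NAMES = FALSE)
    as.integer(out)
  }

  alts <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",",
                   fixed = TRUE)
  n_alt <- lengths(alts)
  rec <- rep(seq_len(nrow(fix)), n_alt)      # record index per output row
  aidx <- unlist(lapply(n_alt, seq_len))     # allele index within record

  chrom <- fix[rec, "CHROM"]
  pos <- as.integer(fix[rec, "POS"])
  ref <- toupper(fix[rec, "REF"])
  alt <- toupper(unname(unlist(alts)))
  multiallelic <- n_alt[rec] > 1L

  dp <- tag("DP")
  ad <- tag("AD")
  t_depth <- nth_int(dp$tumor[rec], 1L)
  n_depth <- nth_int(dp$normal[rec], 1L)
  t_alt <- n_alt_ct <- rep(NA_integer_, length(rec))
  alt_fwd <- alt_rev <- ref_fwd <- ref_rev <- rep(NA_integer_, length(rec))
  f1r2 <- f2r1 <- rep(NA_integer_, length(rec))

  if (caller_name == "strelka2") {
    snv_tags <- lapply(setNames(nm = c("A", "C", "G", "T")),
                       function(b) tag(paste0(b, "U")))
    tar <- tag("TAR"); tir <- tag("TIR")
    tier1 <- function(role, base_vec, recs) {
      out <- rep(NA_integer_, length(recs))
      for (b in c("A", "C", "G", "T")) {
        sel <- which(base_vec == b)
        if (length(sel)) {
          out[sel] <- nth_int(snv_tags[[b]][[role]][recs[sel]], 1L)
        }
      }
      out
    }
    is_snv <- nchar(ref) == 1 & nchar(alt) == 1
    t_alt[is_snv] <- tier1("tumor", alt[is_snv], rec[is_snv])
    n_alt_ct[is_snv] <- tier1("normal", alt[is_snv], rec[is_snv])
    # indels: TIR = alt tier1/tier2, TAR = ref
    t_alt[!is_snv] <- nth_int(tir$tumor[rec[!is_snv]], 1L)
    n_alt_ct[!is_snv] <- nth_int(tir$normal[rec[!is_snv]], 1L)
  } else {
    t_alt <- nth_int(ad$tumor[rec], aidx + 1L)
    n_alt_ct <- nth_int(ad$normal[rec], aidx + 1L)
    if (all(is.na(t_depth))) {
      # fall back to summing AD when DP absent
      sum_ad <- function(x) {
        vapply(x, function(s) {
          if (is.na(s)) NA_integer_ else
            sum(suppressWarnings(as.integer(strsplit(s, ",")[[1]])))
        }, integer(1), USE.NAMES = FALSE)
      }
      t_depth <- sum_ad(ad$tumor[rec])
      n_depth <- sum_ad(ad$normal[rec])
    }
  }

  if (caller_name == "mutect2") {
    sb <- tag("SB")
    ref_fwd <- nth_int(sb$tumor[rec], 1L)
    ref_rev <- nth_int(sb$tumor[rec], 2L)
    alt_fwd <- nth_int(sb$tumor[rec], 3L)
    alt_rev <- nth_int(sb$tumor[rec], 4L)
    fr1 <- tag("F1R2"); fr2 <- tag("F2R1")
    f1r2 <- nth_int(fr1$tumor[rec], aidx + 1L)
    f2r1 <- nth_int(fr2$tumor[rec], aidx + 1L)
  } else if (caller_name == "vardict") {
    ald <- tag("ALD"); rd <- tag("RD")
    alt_fwd <- nth_int(ald$tumor[rec], 1L)
    alt_rev <- nth_int(ald$tumor[rec], 2L)
    ref_fwd <- nth_int(rd$tumor[rec], 1L)
    ref_rev <- nth_int(rd$tumor[rec], 2L)
  }

  out <- tibble(
    caller = caller_name, sample_id = sample_id,
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    tumor_depth = t_depth, tumor_alt = t_alt,
    normal_depth = n_depth, normal_alt = n_alt_ct,
    alt_fwd = alt_fwd, alt_rev = alt_rev,
    ref_fwd = ref_fwd, ref_rev = ref_rev,
    f1r2 = f1r2, f2r1 = f2r1,
    multiallelic = multiallelic,
    strand_unknown = is.na(alt_fwd) | is.na(alt_rev),
    line = rec
  )
  bad <- is.na(out$tumor_alt) | is.na(out$tumor_depth) | out$ref == out$alt
  rejected <- out[bad, ]
  out <- out[!bad, ]
  out$vaf <- ifelse(out$tumor_depth > 0, out$tumor_alt / out$tumor_depth,
                    NA_real_)
  out$line <- NULL
  if (nrow(rejected) > 0) {
    inform(sprintf(
      "read_caller_vcf: %d record(s) in '%s' failed extraction (see attr 'rejected')",
      nrow(rejected), basename(path)
    ))
  }
  attr(out, "rejected") <- rejected
  out
}

empty_caller_variants <- function() {
  tibble(
    caller = character(), sample_id = character(), chrom = character(),
    pos = integer(), ref = character(), alt = character(),
    tumor_depth = integer(), tumor_alt = integer(),
    normal_depth = integer(), normal_alt = integer(),
    alt_fwd = integer(), alt_rev = integer(),
    ref_fwd = integer(), ref_rev = integer(),
    f1r2 = integer(), f2r1 = integer(),
    multiallelic = logical(), strand_unknown = logical(), vaf = double()
  )
}

#' Read all caller VCFs for a cohort directory
#'
#' Looks for files named `<sample>.<caller>.vcf` and binds them into one
#' tidy table (one row per caller call).
#'
#' @param dir Directory containing per-sample, per-caller VCFs.
#' @return A tibble in [read_caller_vcf()] schema.
#' @export
read_caller_vcf_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.vcf$", full.names = TRUE)
  pieces <- lapply(files, function(f) {
    parts <- strsplit(basename(f), ".", fixed = TRUE)[[1]]
    caller <- parts[length(parts) - 1L]
    if (!caller %in% CALLERS) return(NULL)
    sid <- paste(parts[seq_len(length(parts) - 2L)], collapse = ".")
    read_caller_vcf(f, caller, sample_id = sid)
  })
  bind_rows(pieces)
}

#' Sequencing target regions
#'
#' Reads a BED3 file (0-based, half-open) of capture target intervals,
#' merges overlapping or book-ended intervals, and computes the total target
#' size in megabases — the denominator of the plasma mutation burden. When
#' no file is given, an "universal" target is returned that contains every
#' position and uses the SureSelect Human All Exon v6+UTR size of 91.08 Mb
#' as its denominator.
#'
#' @param path BED file path, or `NULL` for the universal default.
#' @param default_mb Denominator used when `path` is `NULL`.
#' @return A `cf_targets` tibble with columns `chrom`, `start`, `end`
#'   (0-based half-open) and attributes `total_mb` and `universal`.
#' @export
read_target_regions <- function(path = NULL, default_mb = 91.08) {
  if (is.null(path)) {
    out <- tibble(chrom = character(), start = integer(), end = integer())
    return(new_targets(out, total_mb = default_mb, universal = TRUE))
  }
  bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         comment = "#")
  if (ncol(bed) < 3) abort("BED file must have at least 3 columns")
  out <- tibble(
    chrom = as.character(bed[[1]]),
    start = as.integer(bed[[2]]),
    end = as.integer(bed[[3]])
  )
  target_regions(out)
}

#' @rdname read_target_regions
#' @param intervals Tibble/data frame with `chrom`, `start`, `end`
#'   (0-based half-open) to construct targets in memory.
#' @export
target_regions <- function(intervals) {
  intervals <- as_tibble(intervals)[, c("chrom", "start", "end")]
  if (any(intervals$start >= intervals$end)) {
    abort("malformed interval: start must be < end (0-based half-open)")
  }
  merged <- intervals |>
    group_by(chrom) |>
    group_modify(function(d, g) {
      ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end),
                            min.gapwidth = 1L)
      tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
    }) |>
    ungroup() |>
    arrange(chrom, start)
  new_targets(merged, total_mb = sum(merged$end - merged$start) / 1e6,
              universal = FALSE)
}

new_targets <- function(df, total_mb, universal) {
  structure(df, total_mb = total_mb, universal = universal,
            class = c("cf_targets", class(df)))
}

#' @rdname read_target_regions
#' @param x A `cf_targets` object.
#' @export
target_mb <- function(x) attr(x, "total_mb")

#' Test whether positions fall inside the target regions
#'
#' @param targets A `cf_targets` object.
#' @param chrom,pos Vectors of chromosome names and 1-based positions.
#' @return Logical vector.
#' @export
in_targets <- function(targets, chrom, pos) {
  if (isTRUE(attr(targets, "universal"))) return(rep(TRUE, length(pos)))
  if (nrow(targets) == 0) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (cc in unique(targets$chrom)) {
    t_sub <- targets[targets$chrom == cc, ]
    sel <- which(chrom == cc)
    if (!length(sel)) next
    ir_t <- IRanges::IRanges(t_sub$start + 1L, t_sub$end)
    ir_v <- IRanges::IRanges(pos[sel], pos[sel])
    out[sel] <- IRanges::overlapsAny(ir_v, ir_t)
  }
  out
}

#' Write target regions as BED3
#'
#' @param targets A `cf_targets` object (must not be universal).
#' @param path Output path.
#' @export
write_target_regions <- function(targets, path) {
  if (isTRUE(attr(targets, "universal"))) {
    abort("universal targets have no intervals to write")
  }
  readr::write_tsv(as_tibble(targets)[, c("chrom", "start", "end")], path,
                   col_names = FALSE)
}

CLINICAL_LEVELS <- list(
  sex = c("Male", "Female"),
  t_stage = c("T1-3", "T4"),
  n_stage = c("N0", "N+"),
  clinical_stage = c("I-III", "IV")
)
CLINICAL_LOGICAL <- c("metastasis", "perineural_invasion",
                      "lymphovascular_invasion", "p16", "event")

#' Read and validate the clinical covariate table
#'
#' Expects a TSV with columns `patient_id`, `age`, `sex`, `t_stage`,
#' `n_stage`, `clinical_stage`, `metastasis`, `perineural_invasion`,
#' `lymphovascular_invasion`, `p16`, `os_time`, `event`. Categorical fields
#' are restricted to the study dichotomies (`T1-3`/`T4`, `N0`/`N+`,
#' `I-III`/`IV`); logical fields accept TRUE/FALSE, yes/no or 0/1. An age
#' dichotomy `age_group` (`<=60` vs `>60`; 60 itself goes to `<=60`) is
#' derived.
#'
#' @param path TSV file path.
#' @return A validated tibble of clinical records.
#' @export
read_clinical_table <- function(path) {
  clin <- readr::read_tsv(path, show_col_types = FALSE)
  validate_clinical(clin)
}

#' @rdname read_clinical_table
#' @param clin A data frame of clinical records to validate in memory.
#' @export
validate_clinical <- function(clin) {
  clin <- as_tibble(clin)
  needed <- c("patient_id", "age", "os_time", names(CLINICAL_LEVELS),
              CLINICAL_LOGICAL)
  missing_cols <- setdiff(needed, names(clin))
  if (length(missing_cols)) {
    abort(paste("clinical table missing columns:",
                paste(missing_cols, collapse = ", ")))
  }
  for (col in names(CLINICAL_LEVELS)) {
    bad <- which(!clin[[col]] %in% CLINICAL_LEVELS[[col]])
    if (length(bad)) {
      abort(sprintf("clinical column '%s', row %d: unknown label '%s'",
                    col, bad[1], clin[[col]][bad[1]]))
    }
  }
  for (col in CLINICAL_LOGICAL) {
    v <- clin[[col]]
    if (!is.logical(v)) {
      lv <- tolower(as.character(v))
      parsed <- ifelse(lv %in% c("true", "yes", "1"), TRUE,
                       ifelse(lv %in% c("false", "no", "0"), FALSE, NA))
      bad <- which(is.na(parsed) & !is.na(v))
      if (length(bad)) {
        abort(sprintf("clinical column '%s', row %d: unknown label '%s'",
                      col, bad[1], as.character(v)[bad[1]]))
      }
      clin[[col]] <- parsed
    }
  }
  if (any(clin$os_time < 0)) abort("os_time must be >= 0")
  clin$age_group <- ifelse(clin$age <= 60, "<=60", ">60")
  clin
}

#' Write (and re-read) the per-variant report
#'
#' One row per merged variant with its caller support, consolidated read
#' evidence, filter trace (semicolon-joined names of fired filters; empty
#' for kept variants) and IGV-style verdict. Column order is stable so
#' reports diff cleanly.
#'
#' @param variants Merged variant tibble (see [merge_callers()]), optionally
#'   carrying `gene`, `consequence` and `igv_verdict` columns.
#' @param path Output TSV path.
#' @param trace Optional filter trace tibble from [apply_cascade()] with
#'   columns `key`, `filter_name`, `fired`.
#' @return The written tibble, invisibly.
#' @export
write_variant_report <- function(variants, path, trace = NULL) {
  cols <- c("key", "sample_id", "chrom", "pos", "ref", "alt", "callers",
            "n_callers", "tumor_depth", "tumor_alt", "normal_depth",
            "normal_alt", "vaf", "gene", "consequence", "filter_trace",
            "igv_verdict")
  out <- as_tibble(variants)
  if (!"filter_trace" %in% names(out)) {
    if (!is.null(trace)) {
      fired_by_key <- trace |>
        filter(fired) |>
        group_by(key) |>
        summarise(filter_trace = paste(filter_name, collapse = ";"))
      out <- left_join(out, fired_by_key, by = "key")
      out$filter_trace <- out$filter_trace %||% ""
      out$filter_trace[is.na(out$filter_trace)] <- ""
    } else {
      out$filter_trace <- ""
    }
  }
  if (!"igv_verdict" %in% names(out)) out$igv_verdict <- "untested"
  for (col in setdiff(cols, names(out))) out[[col]] <- NA
  out <- out[, cols]
  readr::write_tsv(out, path)
  invisible(out)
}

#' @rdname write_variant_report
#' @export
read_variant_report <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    filter_trace = readr::col_character(),
                    igv_verdict = readr::col_character(),
                    chrom = readr::col_character()
                  ))
}
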