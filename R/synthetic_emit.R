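#' Emit per-patient caller VCFs
#'
#' Writes one VCF per patient per caller containing the manifest variants
#' that caller detected, in that caller's FORMAT dialect (see
#' [read_caller_vcf()]). Emission is a deterministic function of the
#' manifest: all randomness (detection, counts) was drawn at simulation
#' time. VarDict output deliberately pads indel alleles with the following
#' reference base, exercising cross-caller normalization.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Tibble of written files (`patient_id`, `caller`, `path`, `n`),
#'   invisibly.
#' @export
emit_caller_vcfs <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mf <- cohort$manifest
  out <- list()
  for (pid in unique(mf$patient_id)) {
    for (caller in CALLERS) {
      rows <- mf[mf$patient_id == pid & mf[[paste0("called_", caller)]], ]
      rows <- rows[order(rows$chrom, rows$pos), ]
      path <- file.path(dir, paste0(pid, ".", caller, ".vcf"))
      writeLines(vcf_lines(rows, caller, cohort$genome$reference), path)
      out[[length(out) + 1L]] <- tibble(patient_id = pid, caller = caller,
                                        path = path, n = nrow(rows))
    }
  }
  invisible(bind_rows(out))
}

vcf_header <- function(caller) {
  fmt <- c(
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=SB,Number=4,Type=Integer,Description="Per-strand ref/alt counts">',
    '##FORMAT=<ID=F1R2,Number=R,Type=Integer,Description="F1R2 pair counts">',
    '##FORMAT=<ID=F2R1,Number=R,Type=Integer,Description="F2R1 pair counts">',
    '##FORMAT=<ID=AF,Number=A,Type=Float,Description="Allele frequency">',
    '##FORMAT=<ID=RD,Number=2,Type=Integer,Description="Ref fwd/rev counts">',
    '##FORMAT=<ID=ALD,Number=2,Type=Integer,Description="Alt fwd/rev counts">',
    '##FORMAT=<ID=AU,Number=2,Type=Integer,Description="A tier counts">',
    '##FORMAT=<ID=CU,Number=2,Type=Integer,Description="C tier counts">',
    '##FORMAT=<ID=GU,Number=2,Type=Integer,Description="G tier counts">',
    '##FORMAT=<ID=TU,Number=2,Type=Integer,Description="T tier counts">',
    '##FORMAT=<ID=TAR,Number=2,Type=Integer,Description="Ref indel tier counts">',
    '##FORMAT=<ID=TIR,Number=2,Type=Integer,Description="Alt indel tier counts">'
  )
  c("##fileformat=VCFv4.2",
    sprintf("##source=cfsomatic-synthetic-%s", caller),
    fmt,
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "TUMOR", "NORMAL", sep = "\t"))
}

vcf_lines <- function(rows, caller, reference) {
  hdr <- vcf_header(caller)
  if (nrow(rows) == 0) return(hdr)
  td <- rows$tumor_depth; ta <- rows$tumor_alt
  nd <- rows$normal_depth; na_ <- rows$normal_alt
  tr <- td - ta; nr <- nd - na_
  ref <- rows$ref; alt <- rows$alt; pos <- rows$pos
  if (caller == "vardict") {
    # suffix-pad indels with the next reference base
    ind <- which(nchar(ref) != nchar(alt))
    for (j in ind) {
      nxt <- substr(reference[[rows$chrom[j]]],
                    pos[j] + nchar(ref[j]), pos[j] + nchar(ref[j]))
      ref[j] <- paste0(ref[j], nxt)
      alt[j] <- paste0(alt[j], nxt)
    }
  }
  body <- switch(
    caller,
    mutect2 = {
      f1_ref <- tr %/% 2L
      f2_ref <- tr - f1_ref
      tum <- sprintf("%d:%d,%d:%d,%d,%d,%d:%d,%d:%d,%d",
                     td, tr, ta,
                     rows$ref_fwd, rows$ref_rev, rows$alt_fwd, rows$alt_rev,
                     f1_ref, rows$f1r2, f2_ref, rows$f2r1)
      nrm <- sprintf("%d:%d,%d:%d,%d,%d,%d:%d,%d:%d,%d",
                     nd, nr, na_,
                     nr %/% 2L, nr - nr %/% 2L, na_ %/% 2L, na_ - na_ %/% 2L,
                     nr %/% 2L, na_ %/% 2L, nr - nr %/% 2L, na_ - na_ %/% 2L)
      paste0("DP:AD:SB:F1R2:F2R1\t", tum, "\t", nrm)
    },
    vardict = {
      tum <- sprintf("%d:%d,%d:%.4f:%d,%d:%d,%d",
                     td, tr, ta, ta / td,
                     rows$ref_fwd, rows$ref_rev, rows$alt_fwd, rows$alt_rev)
      nrm <- sprintf("%d:%d,%d:%.4f:%d,%d:%d,%d",
                     nd, nr, na_, ifelse(nd > 0, na_ / nd, 0),
                     nr %/% 2L, nr - nr %/% 2L, na_ %/% 2L, na_ - na_ %/% 2L)
      paste0("DP:AD:AF:RD:ALD\t", tum, "\t", nrm)
    },
    strelka2 = {
      is_snv <- nchar(ref) == 1 & nchar(alt) == 1
      out <- character(nrow(rows))
      if (any(is_snv)) {
        tier <- function(depth_ref, depth_alt, refb, altb) {
          vapply(c("A", "C", "G", "T"), function(b) {
            cnt <- ifelse(b == altb, depth_alt,
                          ifelse(b == refb, depth_ref, 0L))
            sprintf("%d,%d", cnt, cnt)
          }, character(length(refb)))
        }
        tt <- tier(tr[is_snv], ta[is_snv], ref[is_snv], alt[is_snv])
        nt <- tier(nr[is_snv], na_[is_snv], ref[is_snv], alt[is_snv])
        if (is.null(dim(tt))) { tt <- matrix(tt, nrow = 1); nt <- matrix(nt, nrow = 1) }
        out[is_snv] <- sprintf(
          "DP:AU:CU:GU:TU\t%d:%s:%s:%s:%s\t%d:%s:%s:%s:%s",
          td[is_snv], tt[, 1], tt[, 2], tt[, 3], tt[, 4],
          nd[is_snv], nt[, 1], nt[, 2], nt[, 3], nt[, 4])
      }
      if (any(!is_snv)) {
        out[!is_snv] <- sprintf(
          "DP:TAR:TIR\t%d:%d,%d:%d,%d\t%d:%d,%d:%d,%d",
          td[!is_snv], tr[!is_snv], tr[!is_snv], ta[!is_snv], ta[!is_snv],
          nd[!is_snv], nr[!is_snv], nr[!is_snv], na_[!is_snv], na_[!is_snv])
      }
      out
    },
    # muse / somaticsniper: depth and allelic depths only
    sprintf("DP:AD\t%d:%d,%d\t%d:%d,%d", td, tr, ta, nd, nr, na_)
  )
  c(hdr, paste(rows$chrom, pos, ".", ref, alt, ".", "PASS", ".", body,
               sep = "\t"))
}

#' Emit pileup windows for candidate variants
#'
#' Materializes the read-level pileup windows the validation classifier
#' consumes. True somatic variants get clean biallelic, dual-strand
#' windows with >= 3 alt reads in the tumor and < 3 in the normal; each
#' planted artifact class violates exactly its intended criterion
#' (strand-biased: all alt reads on one strand; clustered-mismatch: every
#' alt read carries at least one extra mismatch in the 20 bp window;
#' low-support: tumor alt reads < 3 or normal alt reads >= 3).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param keys Variant keys to emit (default: all manifest variants —
#'   scale down for large cohorts).
#' @param path Optional TSV output path.
#' @return The pileup tibble (written to `path` if given).
#' @export
emit_pileups <- function(cohort, keys = NULL, path = NULL) {
  mf <- cohort$manifest
  if (!is.null(keys)) mf <- mf[mf$key %in% keys, ]
  set.seed(derive_seed(cohort$config$seed, 3L))
  tum <- pileup_rows(mf, role = "tumor")
  nrm <- pileup_rows(mf, role = "normal")
  out <- bind_rows(tum, nrm)
  if (!is.null(path)) write_pileups(out, path)
  out
}

pileup_rows <- function(mf, role) {
  depth <- if (role == "tumor") mf$tumor_depth else mf$normal_depth
  altn <- if (role == "tumor") mf$tumor_alt else mf$normal_alt
  rows <- rep(seq_len(nrow(mf)), depth)
  widx <- sequence(depth)
  is_alt <- widx <= altn[rows]
  strand <- ifelse(widx %% 2L == 1L, "fwd", "rev")
  if (role == "tumor") {
    sb <- mf$origin[rows] == "strand_bias" & is_alt
    strand[sb] <- "fwd"
  }
  mm <- rpois(length(rows), 0.02)
  if (role == "tumor") {
    cm <- mf$origin[rows] == "cluster_mismatch" & is_alt
    mm[cm] <- 1L + rpois(sum(cm), 0.5)
  }
  tibble(
    key = mf$key[rows],
    role = role,
    read_id = paste0(mf$key[rows], ":", substr(role, 1, 1), widx),
    strand = strand,
    base = ifelse(is_alt, mf$alt[rows], mf$ref[rows]),
    mismatches = as.integer(mm)
  )
}

#' Score a pipeline run against the truth manifest
#'
#' Sensitivity is the fraction of true qualifying somatic variants
#' surviving the cascade; the false discovery rate is the fraction of kept
#' variants that are not true somatics (sub-threshold somatics count as
#' true). Per-origin removal rates attribute each planted class to the
#' filters that caught it.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param kept Kept variant tibble from [apply_cascade()].
#' @param cascade Optional full `cf_cascade` object for per-filter
#'   attribution.
#' @return List: `sensitivity`, `fdr`, `by_origin` tibble (and
#'   `filter_attribution` when `cascade` is supplied).
#' @export
evaluate_pipeline <- function(cohort, kept, cascade = NULL) {
  mf <- cohort$manifest
  if (!all(kept$sample_id %in% mf$patient_id)) {
    abort("kept variants reference samples absent from the manifest")
  }
  truth <- mf$key[mf$origin == "somatic"]
  kept_keys <- kept$key
  true_origins <- c("somatic", "somatic_lowvaf")
  is_true <- kept_keys %in% mf$key[mf$origin %in% true_origins]
  by_origin <- mf |>
    group_by(origin) |>
    summarise(n = n(),
              n_removed = sum(!key %in% kept_keys),
              removal_rate = n_removed / n,
              .groups = "drop")
  out <- list(
    sensitivity = mean(truth %in% kept_keys),
    fdr = if (length(kept_keys)) mean(!is_true) else 0,
    by_origin = by_origin
  )
  if (!is.null(cascade)) {
    out$filter_attribution <- cascade$flags |>
      inner_join(mf |> select(key, origin), by = "key") |>
      tidyr::pivot_longer(-c(key, origin), names_to = "filter_name",
                          values_to = "fired") |>
      group_by(origin, filter_name) |>
      summarise(rate_fired = mean(fired), .groups = "drop") |>
      filter(rate_fired > 0)
  }
  out
}

#' Score the validation classifier against planted labels
#'
#' Accuracy over the classes the read-level criteria are designed to
#' separate: clean somatic variants should PASS; strand-biased,
#' clustered-mismatch and low-support artifacts should not. (oxoG and
#' panel-of-normals artifacts carry clean pileups — they are caught by the
#' orientation and PoN filters upstream — so they are not part of the
#' classifier's denominator.)
#'
#' @param cohort A [simulate_cohort()] result.
#' @param verdicts Output of [classify_variants_igv()].
#' @return List: `accuracy`, `by_class` tibble (`origin`, `n`,
#'   `n_correct`, `expected`).
#' @export
evaluate_igv <- function(cohort, verdicts) {
  expected <- c(somatic = "pass", strand_bias = "non_pass",
                cluster_mismatch = "non_pass", low_support = "non_pass")
  dat <- verdicts |>
    inner_join(cohort$manifest |> select(key, origin), by = "key") |>
    filter(origin %in% names(expected), verdict != "untestable") |>
    mutate(correct = verdict == expected[origin])
  list(
    accuracy = mean(dat$correct),
    by_class = dat |>
      group_by(origin) |>
      summarise(n = n(), n_correct = sum(correct),
                accuracy = mean(correct), .groups = "drop") |>
      mutate(expected = expected[origin])
  )
}

#' Write every cohort artifact to a directory
#'
#' Caller VCFs, clinical TSV, target BED, gene model TSV, reference FASTA,
#' population AF table, PoN site list, and the truth manifest.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory.
#' @param pileups Emit the (large) pileup TSV too? Default FALSE.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, pileups = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emit_caller_vcfs(cohort, file.path(dir, "vcf"))
  readr::write_tsv(cohort$clinical |> select(-age_group),
                   file.path(dir, "clinical.tsv"))
  write_target_regions(cohort$genome$targets, file.path(dir, "targets.bed"))
  write_gene_models(cohort$genome$models, file.path(dir, "genes.tsv"))
  write_reference(cohort$genome$reference, file.path(dir, "reference.fa"))
  readr::write_tsv(cohort$af_table, file.path(dir, "population_af.tsv"))
  writeLines(cohort$pon_sites, file.path(dir, "pon_sites.txt"))
  readr::write_tsv(cohort$manifest, file.path(dir, "truth_manifest.tsv"))
  if (pileups) emit_pileups(cohort, path = file.path(dir, "pileups.tsv"))
  invisible(dir)
}
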