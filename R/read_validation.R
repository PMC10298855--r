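#' Configuration of the pileup-based validation classifier
#'
#' The manual IGV inspection of candidate somatic mutations is automated as
#' four deterministic read-level criteria evaluated on 20 bp pileup windows
#' centered on the variant:
#' (i) clean biallelic configuration — no third allele supported by 2+
#' reads at the center column; (ii) at least one alt-supporting read on
#' each strand; (iii) a clean 20 bp window — an alt read carrying any extra
#' mismatch in the window reaches 2 total mismatches (the variant base
#' included) and is discounted; the site passes when at least one alt read
#' is clean and the clean fraction reaches `min_clean_fraction`;
#' (iv) >= 3 alt reads in the tumor and < 3 in the normal pileup.
#'
#' @param min_clean_fraction Minimum fraction of alt-supporting tumor reads
#'   without extra window mismatches (default 0.5).
#' @param third_allele_tolerance Maximum reads supporting a third allele
#'   before the configuration stops being biallelic (default 1, i.e. a
#'   single stray sequencing-error read is tolerated).
#' @param min_tumor_alt_reads,max_normal_alt_reads Alt-read thresholds of
#'   criterion (iv); the normal bound is exclusive (default 3 and 3:
#'   tumor >= 3 and normal < 3).
#' @param window_rule `"per_read"` (default) discounts individual dirty alt
#'   reads; `"per_column"` passes the site when the mean number of extra
#'   window mismatches per alt read is below 1.
#' @return A `cf_igv_config` list.
#' @export
igv_config <- function(min_clean_fraction = 0.5,
                       third_allele_tolerance = 1L,
                       min_tumor_alt_reads = 3L,
                       max_normal_alt_reads = 3L,
                       window_rule = c("per_read", "per_column")) {
  structure(
    list(min_clean_fraction = min_clean_fraction,
         third_allele_tolerance = as.integer(third_allele_tolerance),
         min_tumor_alt_reads = as.integer(min_tumor_alt_reads),
         max_normal_alt_reads = as.integer(max_normal_alt_reads),
         window_rule = match.arg(window_rule)),
    class = "cf_igv_config"
  )
}

#' Read a pileup window table
#'
#' A deliberately simple interchange format: one row per read per window
#' with columns `key` (variant key), `role` (`tumor`/`normal`), `read_id`,
#' `strand` (`fwd`/`rev`/`unknown`), `base` (base called at the variant
#' position, `-` for a gap) and `mismatches` (count of non-reference
#' aligned bases within the 20 bp window, excluding the center position).
#'
#' @param path TSV path.
#' @return Tibble of pileup reads.
#' @export
read_pileups <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    key = readr::col_character(),
                    role = readr::col_character(),
                    read_id = readr::col_character(),
                    strand = readr::col_character(),
                    base = readr::col_character(),
                    mismatches = readr::col_integer()
                  ))
}

#' @rdname read_pileups
#' @param pileups Tibble of pileup reads to write.
#' @export
write_pileups <- function(pileups, path) {
  readr::write_tsv(pileups, path)
  invisible(pileups)
}

#' Single-variant validation criteria
#'
#' Per-criterion checks on one variant's pileup window, matching the four
#' true-positive rules. These are convenience wrappers around the
#' vectorized [classify_variants_igv()]; each takes the tumor (and for
#' [check_alt_counts()] also the normal) pileup subset of a single variant.
#'
#' @param tumor_pileup,normal_pileup Pileup tibbles for one variant
#'   (columns `strand`, `base`, `mismatches`).
#' @param ref,alt Reference and alternate base at the center.
#' @param config An [igv_config()].
#' @return Logical scalar.
#' @name igv_criteria
NULL

#' @rdname igv_criteria
#' @export
check_allele_config <- function(tumor_pileup, ref, alt,
                                config = igv_config()) {
  counts <- table(tumor_pileup$base)
  third <- counts[!names(counts) %in% c(ref, alt)]
  all(third <= config$third_allele_tolerance)
}

#' @rdname igv_criteria
#' @export
check_strand_support <- function(tumor_pileup, alt, config = igv_config()) {
  alt_reads <- tumor_pileup[tumor_pileup$base == alt, ]
  if (nrow(alt_reads) > 0 && all(alt_reads$strand == "unknown")) {
    return(TRUE)  # untestable: strand-unknown evidence is exempt
  }
  any(alt_reads$strand == "fwd") && any(alt_reads$strand == "rev")
}

#' @rdname igv_criteria
#' @export
check_window_clean <- function(tumor_pileup, alt, config = igv_config()) {
  alt_reads <- tumor_pileup[tumor_pileup$base == alt, ]
  if (nrow(alt_reads) == 0) return(FALSE)
  if (config$window_rule == "per_column") {
    return(mean(alt_reads$mismatches) < 1)
  }
  clean <- alt_reads$mismatches == 0
  any(clean) && mean(clean) >= config$min_clean_fraction
}

#' @rdname igv_criteria
#' @export
check_alt_counts <- function(tumor_pileup, normal_pileup, alt,
                             config = igv_config()) {
  sum(tumor_pileup$base == alt) >= config$min_tumor_alt_reads &&
    sum(normal_pileup$base == alt) < config$max_normal_alt_reads
}

#' Classify candidate variants from pileup windows
#'
#' Applies the four true-positive criteria to every variant with pileup
#' data. The verdict is `pass` iff all four criteria hold, `non_pass` if
#' any fails, and `untestable` when the tumor or normal pileup window is
#' missing (untestable variants are excluded from pass-rate denominators).
#' The verdict is a pure function of the pileups and the variant alleles.
#'
#' @param variants Variant tibble with `key`, `ref`, `alt` (and optionally
#'   `gene`) columns.
#' @param pileups Pileup tibble as from [read_pileups()].
#' @param config An [igv_config()].
#' @return Tibble: `key`, the four criterion logicals (`allele_config`,
#'   `strand_support`, `window_clean`, `alt_counts`), and `verdict`.
#' @export
classify_variants_igv <- function(variants, pileups,
                                  config = igv_config()) {
  variants <- as_tibble(variants)
  stats_by_key <- pileups |>
    inner_join(variants |> select(key, ref, alt), by = "key") |>
    group_by(key) |>
    summarise(
      has_tumor = any(role == "tumor"),
      has_normal = any(role == "normal"),
      # criterion counts on the tumor window
      t_alt = sum(role == "tumor" & base == alt),
      t_alt_fwd = sum(role == "tumor" & base == alt & strand == "fwd"),
      t_alt_rev = sum(role == "tumor" & base == alt & strand == "rev"),
      t_alt_known = sum(role == "tumor" & base == alt &
                          strand != "unknown"),
      max_third = max_third_allele(base[role == "tumor"],
                                   ref[1], alt[1]),
      n_clean = sum(role == "tumor" & base == alt & mismatches == 0),
      mean_mm = if (t_alt > 0)
        mean(mismatches[role == "tumor" & base == alt]) else NA_real_,
      n_alt_normal = sum(role == "normal" & base == alt),
      .groups = "drop"
    )
  res <- variants |>
    select(key) |>
    left_join(stats_by_key, by = "key") |>
    mutate(
      untestable = is.na(has_tumor) | !has_tumor | !has_normal,
      allele_config = max_third <= config$third_allele_tolerance,
      strand_support = (t_alt > 0 & t_alt_known == 0) |
        (t_alt_fwd >= 1 & t_alt_rev >= 1),
      window_clean = if (config$window_rule == "per_column") {
        t_alt > 0 & !is.na(mean_mm) & mean_mm < 1
      } else {
        t_alt > 0 & n_clean >= 1 &
          n_clean / pmax(t_alt, 1L) >= config$min_clean_fraction
      },
      alt_counts = t_alt >= config$min_tumor_alt_reads &
        n_alt_normal < config$max_normal_alt_reads,
      verdict = case_when(
        untestable ~ "untestable",
        allele_config & strand_support & window_clean & alt_counts ~ "pass",
        TRUE ~ "non_pass"
      )
    ) |>
    select(key, allele_config, strand_support, window_clean, alt_counts,
           verdict)
  n_untestable <- sum(res$verdict == "untestable")
  if (n_untestable > 0) {
    inform(sprintf("classify_variants_igv: %d variant(s) untestable (missing pileup)",
                   n_untestable))
  }
  res
}

max_third_allele <- function(bases, ref, alt) {
  third <- bases[!bases %in% c(ref, alt)]
  if (length(third) == 0) return(0L)
  max(table(third))
}

#' Per-gene false-positive summary
#'
#' Tabulates validation verdicts by gene: totals, PASS and non-PASS counts
#' with percentages (one decimal), sorted by non-PASS percentage
#' descending. Accepts either a verdict table (with a `verdict` column,
#' joined to genes via the `gene` column or a separate `key`-to-`gene`
#' map) or a pre-tabulated counts table with `gene`, `total` and `pass`
#' columns — the form in which published validation tables are reported.
#'
#' @param x Verdict tibble from [classify_variants_igv()] (with `gene`), or
#'   a counts tibble with columns `gene`, `total`, `pass`.
#' @param genes Optional tibble `key`, `gene` to attach gene symbols.
#' @return Tibble: `gene`, `total`, `pass`, `non_pass`, `pass_pct`,
#'   `non_pass_pct`.
#' @export
gene_fp_summary <- function(x, genes = NULL) {
  x <- as_tibble(x)
  if (!is.null(genes)) x <- left_join(x, genes, by = "key")
  if (all(c("total", "pass") %in% names(x))) {
    counts <- x |> mutate(total = as.integer(total), pass = as.integer(pass))
  } else {
    stopifnot("verdict" %in% names(x), "gene" %in% names(x))
    counts <- x |>
      filter(verdict != "untestable") |>
      group_by(gene) |>
      summarise(total = n(), pass = sum(verdict == "pass"),
                .groups = "drop")
  }
  counts |>
    mutate(non_pass = total - pass,
           pass_pct = round(100 * pass / total, 1),
           non_pass_pct = round(100 * non_pass / total, 1)) |>
    arrange(desc(non_pass_pct), gene)
}

#' Correlation between gene mutation level and false-positive load
#'
#' Tie-corrected Spearman correlation between each gene's total mutation
#' count and its non-PASS (false-positive) count, quantifying whether
#' heavily mutated genes accumulate proportionally more artifacts.
#'
#' @param gene_table Output of [gene_fp_summary()] (>= 3 genes).
#' @return Tibble with `rho` and `p_value`.
#' @export
fp_burden_correlation <- function(gene_table) {
  if (nrow(gene_table) < 3) abort("need at least 3 genes")
  spearman_corr(gene_table$total, gene_table$non_pass)
}
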