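#' Minimal gene models
#'
#' A gene model is one transcript per gene: a set of non-overlapping,
#' sorted exon intervals (1-based inclusive) on one strand whose
#' concatenation is the coding sequence (CDS, length divisible by 3,
#' starting at ATG). This is the stand-in for a full annotation engine:
#' rich transcript ontologies are collapsed to the nine consequence
#' categories used throughout the package.
#'
#' @param path TSV with columns `gene`, `chrom`, `strand` (`+`/`-`),
#'   `start`, `end` (one row per exon).
#' @return Tibble of exon rows.
#' @export
read_gene_models <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    gene = readr::col_character(),
                    chrom = readr::col_character(),
                    strand = readr::col_character(),
                    start = readr::col_integer(),
                    end = readr::col_integer()
                  ))
}

#' @rdname read_gene_models
#' @param models Gene model tibble to write.
#' @export
write_gene_models <- function(models, path) {
  readr::write_tsv(models, path)
  invisible(models)
}

#' Read/write a reference genome FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of chromosome sequences.
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_reference
#' @param reference Named character vector of sequences to write.
#' @export
write_reference <- function(reference, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(reference), path, width = 80L
  )
  invisible(reference)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}
comp_base <- function(b) chartr("ACGT", "TGCA", b)

#' Assign variants to genes
#'
#' A variant belongs to a gene when its position falls inside the gene
#' span (first to last exon) extended by the splice-site margin.
#'
#' @param variants Variant tibble with `chrom`, `pos`.
#' @param models Gene model tibble ([read_gene_models()] schema).
#' @param margin Splice-site margin in bp (default 2).
#' @return `variants` with a `gene` column (`NA` when unassigned).
#' @export
assign_genes <- function(variants, models, margin = 2L) {
  spans <- models |>
    group_by(gene, chrom) |>
    summarise(start = min(start) - margin, end = max(end) + margin,
              .groups = "drop")
  variants <- as_tibble(variants)
  variants$gene <- NA_character_
  for (cc in unique(spans$chrom)) {
    sp <- spans[spans$chrom == cc, ]
    sel <- which(variants$chrom == cc)
    if (!length(sel)) next
    hit <- IRanges::findOverlaps(
      IRanges::IRanges(variants$pos[sel], variants$pos[sel]),
      IRanges::IRanges(sp$start, sp$end),
      select = "first"
    )
    variants$gene[sel] <- sp$gene[hit]
  }
  variants
}

build_cds_index <- function(models, reference) {
  # per gene: exon table with cumulative CDS offsets, plus the CDS string
  models <- models |> arrange(gene, start)
  by_gene <- split(models, models$gene)
  lapply(by_gene, function(ex) {
    ex$width <- ex$end - ex$start + 1L
    ex$cum_before <- cumsum(c(0L, ex$width[-nrow(ex)]))
    L <- sum(ex$width)
    seq <- reference[[ex$chrom[1]]]
    cds_fwd <- paste0(substring(seq, ex$start, ex$end), collapse = "")
    minus <- ex$strand[1] == "-"
    list(exons = ex, L = L, strand = ex$strand[1],
         cds = if (minus) revcomp(cds_fwd) else cds_fwd)
  })
}

#' Classify variant consequences against minimal gene models
#'
#' Codon-level classification on the coding strand. A position within
#' `margin` bp outside an exon is a `splicing_site`; an exonic indel is
#' `frameshift` or `in_frame` by length modulo 3; an exonic SNV is
#' classified by translating the reference and mutated codons:
#' `start_lost` (first codon changed), `stop_retained`/`stop_lost`
#' (reference stop codon), `stop_gained` (new stop), `synonymous`
#' (identical amino acid), otherwise `missense`. Variants outside every
#' exon and splice margin are an error — candidate somatic variants are
#' expected to come from the captured coding space. When `variants`
#' already carries a `consequence` column (e.g. from an external
#' annotator) it is returned untouched.
#'
#' @param variants Variant tibble (`chrom`, `pos`, `ref`, `alt`).
#' @param models Gene model tibble.
#' @param reference Named character vector of chromosome sequences.
#' @param margin Splice-site margin in bp (default 2).
#' @return `variants` with `gene` and `consequence` columns.
#' @export
classify_consequences <- function(variants, models, reference,
                                  margin = 2L) {
  variants <- as_tibble(variants)
  if ("consequence" %in% names(variants) &&
      !all(is.na(variants$consequence))) {
    return(variants)
  }
  reference <- as_reference(reference)
  if (!"gene" %in% names(variants) || all(is.na(variants$gene))) {
    variants <- assign_genes(variants, models, margin)
  }
  idx <- build_cds_index(models, reference)
  code <- Biostrings::GENETIC_CODE
  variants$consequence <- NA_character_
  if (nrow(variants) == 0) return(variants)
  by_gene <- split(seq_len(nrow(variants)), variants$gene)
  for (g in names(by_gene)) {
    gi <- idx[[g]]
    if (is.null(gi)) next
    rows <- by_gene[[g]]
    ex <- gi$exons
    pos <- variants$pos[rows]
    refa <- variants$ref[rows]
    alta <- variants$alt[rows]
    # exon membership and CDS coordinate
    hit <- IRanges::findOverlaps(
      IRanges::IRanges(pos, pos),
      IRanges::IRanges(ex$start, ex$end),
      select = "first"
    )
    in_exon <- !is.na(hit)
    cds_pos <- rep(NA_integer_, length(pos))
    cds_pos[in_exon] <- ex$cum_before[hit[in_exon]] +
      (pos[in_exon] - ex$start[hit[in_exon]] + 1L)
    if (gi$strand == "-") cds_pos <- gi$L - cds_pos + 1L

    is_indel <- nchar(refa) != nchar(alta)
    is_snv <- nchar(refa) == 1L & nchar(alta) == 1L
    out <- rep(NA_character_, length(pos))

    # splice sites: within margin bp outside an exon
    near_splice <- !in_exon & vapply(pos, function(p) {
      any((ex$start - p) %in% seq_len(margin) |
            (p - ex$end) %in% seq_len(margin))
    }, logical(1))
    out[near_splice] <- "splicing_site"

    sel <- in_exon & is_indel
    out[sel] <- ifelse(abs(nchar(refa[sel]) - nchar(alta[sel])) %% 3 == 0,
                       "in_frame", "frameshift")

    sel <- which(in_exon & is_snv)
    if (length(sel)) {
      cp <- cds_pos[sel]
      codon_idx <- (cp - 1L) %/% 3L + 1L
      offset <- (cp - 1L) %% 3L + 1L
      old_codon <- substring(gi$cds, 3L * codon_idx - 2L, 3L * codon_idx)
      new_base <- if (gi$strand == "-") comp_base(alta[sel]) else alta[sel]
      new_codon <- old_codon
      substr(new_codon, offset, offset) <- new_base
      old_aa <- unname(code[old_codon])
      new_aa <- unname(code[new_codon])
      out[sel] <- case_when(
        codon_idx == 1L & new_codon != old_codon ~ "start_lost",
        old_aa == "*" & new_aa == "*" ~ "stop_retained",
        old_aa == "*" & new_aa != "*" ~ "stop_lost",
        new_aa == "*" ~ "stop_gained",
        old_aa == new_aa ~ "synonymous",
        TRUE ~ "missense"
      )
    }
    # equal-length multi-base substitutions: amino-acid altering
    sel <- in_exon & !is_indel & !is_snv
    out[sel] <- "missense"
    variants$consequence[rows] <- out
  }
  bad <- is.na(variants$consequence)
  if (any(bad)) {
    abort(sprintf(
      "%d variant(s) not classifiable (outside exons and splice margins), first at %s:%d",
      sum(bad), variants$chrom[which(bad)[1]], variants$pos[which(bad)[1]]
    ))
  }
  variants
}

#' Nonsynonymous consequence predicate
#'
#' All consequence types alter the protein except `synonymous` and
#' `stop_retained` (a stop codon replaced by another stop leaves the
#' translated product unchanged).
#'
#' @param consequence Character vector of consequence types.
#' @return Logical vector.
#' @export
is_nonsynonymous <- function(consequence) {
  !consequence %in% c("synonymous", "stop_retained")
}

#' Patient-by-gene nonsynonymous mutation matrix
#'
#' Presence/absence (not counts): a cell is `TRUE` iff the patient carries
#' at least one kept nonsynonymous variant in the gene.
#'
#' @param variants Annotated, kept variant tibble with `sample_id`,
#'   `gene`, `consequence`.
#' @param patients Character vector of all patient IDs (so patients with
#'   zero mutations keep a row).
#' @param genes Optional fixed gene set for the columns; defaults to all
#'   genes observed with a nonsynonymous mutation.
#' @return A `cf_gene_matrix` tibble: `patient_id` plus one logical column
#'   per gene.
#' @export
build_gene_matrix <- function(variants, patients, genes = NULL) {
  ns <- variants |>
    filter(!is.na(gene), is_nonsynonymous(consequence)) |>
    distinct(sample_id, gene) |>
    mutate(mutated = TRUE)
  if (is.null(genes)) genes <- sort(unique(ns$gene))
  wide <- tidyr::expand_grid(patient_id = patients, gene = genes) |>
    left_join(ns, by = c(patient_id = "sample_id", "gene")) |>
    mutate(mutated = !is.na(mutated)) |>
    tidyr::pivot_wider(names_from = gene, values_from = mutated)
  structure(wide, class = c("cf_gene_matrix", class(wide)))
}

#' Per-gene mutation frequencies
#'
#' @param matrix A [build_gene_matrix()] result.
#' @return Tibble `gene`, `n_mutated`, `frequency`.
#' @export
gene_frequencies <- function(matrix) {
  genes <- setdiff(names(matrix), "patient_id")
  n <- nrow(matrix)
  tibble(
    gene = genes,
    n_mutated = vapply(genes, function(g) sum(matrix[[g]]), integer(1),
                       USE.NAMES = FALSE),
    frequency = vapply(genes, function(g) mean(matrix[[g]]), double(1),
                       USE.NAMES = FALSE)
  )
}

#' Most frequently mutated genes
#'
#' Ranked by patient frequency descending; ties broken lexicographically
#' by gene symbol.
#'
#' @param matrix A [build_gene_matrix()] result.
#' @param n Number of genes to return.
#' @return Tibble `gene`, `n_mutated`, `frequency`, ranked.
#' @export
top_mutated_genes <- function(matrix, n = 20L) {
  stopifnot(n >= 1)
  gene_frequencies(matrix) |>
    arrange(desc(frequency), gene) |>
    head(n)
}
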