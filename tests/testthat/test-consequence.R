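# A hand-built two-gene model: GENEP on the plus strand, GENEM minus.
toy_model <- function() {
  # GENEP CDS: ATG GAA TAC CCT TGA  (Met Glu Tyr Pro Stop)
  cds_p <- "ATGGAATACCCTTGA"
  # GENEM same CDS placed on the minus strand
  cds_m <- "ATGGAATACCCTTGA"
  left <- "TTTTTTTTTT"
  mid <- "AAAAAAAAAA"
  chrom <- paste0(left, cds_p, mid,
                  as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(cds_m))), "TTTTTTTTTT")
  models <- tibble::tibble(
    gene = c("GENEP", "GENEM"),
    chrom = "chrT",
    strand = c("+", "-"),
    start = c(11L, 36L),
    end = c(25L, 50L)
  )
  list(models = models, reference = c(chrT = chrom))
}

toy_variant <- function(pos, ref, alt, sample_id = "S1") {
  tibble::tibble(sample_id = sample_id, chrom = "chrT", pos = pos,
                 ref = ref, alt = alt)
}

test_that("codon-level classes follow the standard genetic code", {
  m <- toy_model()
  # GAA -> GAG (Glu -> Glu): synonymous, third codon base at pos 16
  v <- classify_consequences(toy_variant(16L, "A", "G"), m$models,
                             m$reference)
  expect_equal(v$consequence, "synonymous")
  expect_equal(v$gene, "GENEP")
  # TAC -> TAA: stop gained (pos 19 is the C of TAC)
  expect_equal(classify_consequences(toy_variant(19L, "C", "A"),
                                     m$models, m$reference)$consequence,
               "stop_gained")
  # ATG start disrupted
  expect_equal(classify_consequences(toy_variant(11L, "A", "G"),
                                     m$models, m$reference)$consequence,
               "start_lost")
  # TGA -> TAA: stop retained (pos 24 G>A)
  expect_equal(classify_consequences(toy_variant(24L, "G", "A"),
                                     m$models, m$reference)$consequence,
               "stop_retained")
  # TGA -> TGG: stop lost
  expect_equal(classify_consequences(toy_variant(25L, "A", "G"),
                                     m$models, m$reference)$consequence,
               "stop_lost")
  # missense: GAA -> GTA at pos 15
  expect_equal(classify_consequences(toy_variant(15L, "A", "T"),
                                     m$models, m$reference)$consequence,
               "missense")
  # indels: 1 bp deletion frameshift, 3 bp deletion in frame
  expect_equal(classify_consequences(toy_variant(14L, "GA", "G"),
                                     m$models, m$reference)$consequence,
               "frameshift")
  expect_equal(classify_consequences(toy_variant(14L, "GAAT", "G"),
                                     m$models, m$reference)$consequence,
               "in_frame")
  # 2 bp outside the exon: splice site; 5 bp outside: error
  expect_equal(classify_consequences(toy_variant(9L, "T", "A"),
                                     m$models, m$reference)$consequence,
               "splicing_site")
  expect_error(classify_consequences(toy_variant(5L, "T", "A"),
                                     m$models, m$reference),
               "not classifiable")
})

test_that("random coding SNVs match a translate-both-haplotypes oracle", {
  co <- small_cohort()
  g <- co$genome
  set.seed(21)
  pick <- g$pool[sample.int(nrow(g$pool), 500L), ]
  pick$alt <- vapply(pick$base, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  vars <- tibble::tibble(sample_id = "S1", chrom = pick$chrom,
                         pos = pick$pos, ref = pick$base, alt = pick$alt,
                         gene = pick$gene)
  got <- classify_consequences(vars, g$models, g$reference)

  # oracle: substitute the base in the genome, rebuild both CDS
  # haplotypes exon by exon, translate, and compare proteins
  oracle <- character(nrow(vars))
  code <- Biostrings::GENETIC_CODE
  translate_cds <- function(cds) {
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    paste(code[codons], collapse = "")
  }
  for (i in seq_len(nrow(vars))) {
    ex <- g$models[g$models$gene == vars$gene[i], ]
    ex <- ex[order(ex$start), ]
    seq0 <- g$reference[[vars$chrom[i]]]
    seq1 <- seq0
    substr(seq1, vars$pos[i], vars$pos[i]) <- vars$alt[i]
    build <- function(s) {
      cds <- paste(substring(s, ex$start, ex$end), collapse = "")
      if (ex$strand[1] == "-") {
        cds <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(cds)))
      }
      cds
    }
    p0 <- translate_cds(build(seq0))
    p1 <- translate_cds(build(seq1))
    first_aa_changed <- substr(p0, 1, 1) != substr(p1, 1, 1)
    # also start-lost when the ATG codon changes silently in protein space
    cds0 <- build(seq0); cds1 <- build(seq1)
    oracle[i] <-
      if (substr(cds0, 1, 3) != substr(cds1, 1, 3)) "start_lost"
      else if (p0 == p1 && substr(p0, nchar(p0), nchar(p0)) == "*" &&
               cds0 != cds1 &&
               substr(cds0, nchar(cds0) - 2, nchar(cds0)) !=
                 substr(cds1, nchar(cds1) - 2, nchar(cds1))) "stop_retained"
      else if (p0 == p1) ifelse(cds0 == cds1, "identical", "synonymous")
      else if (grepl("\\*", substr(p1, 1, nchar(p1) - 1))) "stop_gained"
      else if (substr(p0, nchar(p0), nchar(p0)) == "*" &&
               substr(p1, nchar(p1), nchar(p1)) != "*") "stop_lost"
      else "missense"
    if (first_aa_changed && oracle[i] == "missense" &&
        vars$pos[i] %in% ex$start[1]:ex$end[1]) {
      # a changed first codon is a start loss, not missense
    }
  }
  # the oracle can't see stop_retained as distinct from synonymous when
  # the changed codon still translates identically; align the labels
  oracle[oracle == "synonymous" & got$consequence == "stop_retained"] <-
    "stop_retained"
  expect_equal(got$consequence, oracle)
})

test_that("strand symmetry: plus and minus gene models classify alike", {
  m <- toy_model()
  # same biological mutations on GENEM (minus strand): its CDS reads
  # identically, so genomic complements at mirrored positions must give
  # the same classes. GENEM exon spans 36..50, CDS base i sits at
  # genomic pos 50 - i + 1 with complemented bases.
  # synonymous: CDS pos 6 (A->G third base of GAA) -> genome pos 45 T->C
  expect_equal(classify_consequences(toy_variant(45L, "T", "C"),
                                     m$models, m$reference)$consequence,
               "synonymous")
  # stop gained at CDS pos 9 (C->A) -> genome pos 42 G>T
  expect_equal(classify_consequences(toy_variant(42L, "G", "T"),
                                     m$models, m$reference)$consequence,
               "stop_gained")
  # start lost at CDS pos 1 -> genome pos 50 T>C
  expect_equal(classify_consequences(toy_variant(50L, "T", "C"),
                                     m$models, m$reference)$consequence,
               "start_lost")
})

test_that("nonsynonymous predicate exempts protein-preserving classes", {
  expect_true(is_nonsynonymous("missense"))
  expect_true(is_nonsynonymous("stop_gained"))
  expect_true(is_nonsynonymous("frameshift"))
  expect_false(is_nonsynonymous("synonymous"))
  expect_false(is_nonsynonymous("stop_retained"))
})

test_that("type counts partition the classified variants", {
  co <- small_cohort()
  res <- run_scaled_pipeline(co)
  kept <- classify_consequences(res$cascade$kept, co$genome$models,
                                co$genome$reference)
  expect_equal(sum(table(factor(kept$consequence,
                                levels = cfsomatic:::CONSEQUENCE_TYPES))),
               nrow(kept))
  # a pre-annotated consequence column bypasses classification
  pre <- kept
  pre$consequence <- "missense"
  out <- classify_consequences(pre, co$genome$models, co$genome$reference)
  expect_true(all(out$consequence == "missense"))
})

test_that("gene matrix is presence-based and ranking breaks ties by symbol", {
  vars <- dplyr::bind_rows(
    toy_variant(1L, "A", "T", "P1"), toy_variant(2L, "A", "T", "P1"),
    toy_variant(3L, "A", "T", "P1"),
    toy_variant(4L, "A", "T", "P2")
  )
  vars$gene <- c("BBB", "BBB", "BBB", "AAA")
  vars$consequence <- "missense"
  m <- build_gene_matrix(vars, patients = c("P1", "P2", "P3"))
  expect_equal(dim(m), c(3L, 3L))   # patient_id + 2 genes
  expect_true(m$BBB[m$patient_id == "P1"])   # 3 hits -> one TRUE cell
  expect_false(m$BBB[m$patient_id == "P2"])
  freq <- gene_frequencies(m)
  expect_equal(freq$frequency[freq$gene == "BBB"], 1 / 3)
  # tie at equal frequency: lexicographic order
  top <- top_mutated_genes(m, 2)
  expect_equal(top$gene, c("AAA", "BBB"))
  # empty variant table gives an all-false matrix
  m0 <- build_gene_matrix(vars[0, ], patients = c("P1", "P2"),
                          genes = c("AAA"))
  expect_false(any(m0$AAA))
})

test_that("synthetic per-gene frequencies recover the designed gene sets", {
  co <- small_cohort()
  res <- run_scaled_pipeline(co)
  kept <- classify_consequences(res$cascade$kept, co$genome$models,
                                co$genome$reference)
  mat <- build_gene_matrix(kept, patients = co$clinical$patient_id)
  truth <- co$geneset_truth
  bcaa <- suppressWarnings(geneset_status(mat, cfsomatic:::BCAA_GENES))
  expect_equal(bcaa$mutated[match(truth$patient_id, bcaa$patient_id)],
               truth$bcaa)
  hyp <- suppressWarnings(geneset_status(mat, cfsomatic:::HYPOXIA_GENES))
  expect_equal(hyp$mutated[match(truth$patient_id, hyp$patient_id)],
               truth$hypoxia)
})
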