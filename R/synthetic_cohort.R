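#' Simulation configuration for a synthetic cfDNA study
#'
#' Defines the study conditions a generated cohort emulates: 50 patients of
#' whom 9 are metastatic, with plasma mutation burdens of 14 vs 38
#' qualifying (VAF >= 5%) somatic mutations per Mb in the non-metastatic
#' and metastatic groups — the group means reported for cohorts of this
#' kind — plus germline SNPs carrying population allele frequencies,
#' artifact classes that each violate one specific filter or validation
#' criterion, caller-specific sensitivity/false-positive profiles for the
#' five emitted VCF dialects, and survival times coupled to gene-set
#' mutation status. Per-patient qualifying somatic counts are Poisson with
#' rate `lambda * target_mb`. The synthetic exome is a small gene space
#' (defaults to ~4.5 Mb of coding sequence) while `target_mb` stays at
#' 91.08 as the burden denominator, preserving the scale of the statistic
#' at desk-scale runtime.
#'
#' @param seed Master seed; every derived stream comes from it.
#' @param n_patients Cohort size (default 50).
#' @param metastatic_fraction Fraction of metastatic patients (default
#'   9/50; the count is fixed, not resampled).
#' @param lambda_nonmet,lambda_met Qualifying somatic mutations per Mb for
#'   the two groups (defaults 14 and 38).
#' @param lambda_subthreshold Rate (per Mb) of true somatics with VAF in
#'   the 2-5% band, below the default burden threshold (default 3).
#' @param germline_snps Germline SNPs per patient, all with population MAF
#'   > 1% (default 200).
#' @param artifacts_per_patient Named counts of planted artifact variants
#'   per patient for classes `oxog`, `strand_bias`, `cluster_mismatch`,
#'   `low_support`, `blacklist_fp`.
#' @param n_position_clusters Planted clusters of 3 artifact variants
#'   within < 100 bp, per patient.
#' @param n_pon_sites Number of recurrent-artifact loci in the panel of
#'   normals; each patient carries each with probability
#'   `pon_recurrence`.
#' @param pon_recurrence Per-patient probability of a PoN site.
#' @param caller_sensitivity Named per-caller detection probability for
#'   true variants.
#' @param artifact_detection Per-caller detection probability for
#'   systematic artifacts (shared damage/mapping errors recur across
#'   callers, so this is high; default 0.98).
#' @param caller_fp_per_patient Named counts of caller-private
#'   false-positive calls (low allele support) per patient.
#' @param vaf_shape1,vaf_shape2 Beta parameters of the true somatic VAF
#'   distribution (truncated at 0.05 for qualifying variants).
#' @param depth_mean Mean sequencing depth (reads) at a variant site.
#' @param indel_fraction Fraction of uniform somatic variants that are
#'   small indels.
#' @param baseline_hazard Daily exponential death hazard for gene-set
#'   wild-type patients (default log(2)/1095: three-year median survival).
#' @param geneset_hr Hazard ratio for patients with a mutated survival
#'   gene set (default 3).
#' @param censor_range Uniform range (days) of administrative censoring.
#' @param bcaa_fraction,hypoxia_fraction Fractions of patients carrying a
#'   mutation in the BCAA-catabolism and hypoxia-related gene sets
#'   (defaults 0.24 and 0.30).
#' @param metastasis_gene Gene planted with a nonsynonymous mutation in
#'   every metastatic patient (and `metastasis_gene_bg` of the rest).
#' @param metastasis_gene_bg Background mutation probability of
#'   `metastasis_gene` in non-metastatic patients.
#' @param target_mb PMB denominator in megabases (default 91.08).
#' @param n_filler_genes,cds_codons,exons_per_gene,intron_bp,gene_gap_bp,n_chroms
#'   Synthetic genome dimensions: filler genes beyond the 35 named ones,
#'   codons per CDS, exons per gene, intron and intergenic spacer sizes,
#'   number of chromosomes.
#' @return A `cf_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 50L,
                       metastatic_fraction = 9 / 50,
                       lambda_nonmet = 14,
                       lambda_met = 38,
                       lambda_subthreshold = 3,
                       germline_snps = 200L,
                       artifacts_per_patient = c(oxog = 15L,
                                                 strand_bias = 15L,
                                                 cluster_mismatch = 15L,
                                                 low_support = 15L,
                                                 blacklist_fp = 5L),
                       n_position_clusters = 5L,
                       n_pon_sites = 30L,
                       pon_recurrence = 0.4,
                       caller_sensitivity = c(muse = 0.75, mutect2 = 0.90,
                                              strelka2 = 0.85,
                                              somaticsniper = 0.70,
                                              vardict = 0.80),
                       artifact_detection = 0.98,
                       caller_fp_per_patient = c(muse = 30L, mutect2 = 5L,
                                                 strelka2 = 60L,
                                                 somaticsniper = 25L,
                                                 vardict = 55L),
                       vaf_shape1 = 2, vaf_shape2 = 8,
                       depth_mean = 90,
                       indel_fraction = 0.005,
                       baseline_hazard = log(2) / 1095,
                       geneset_hr = 3,
                       censor_range = c(500, 2500),
                       bcaa_fraction = 0.24,
                       hypoxia_fraction = 0.30,
                       metastasis_gene = "KMT2D",
                       metastasis_gene_bg = 0.1,
                       target_mb = 91.08,
                       n_filler_genes = 215L,
                       cds_codons = 6000L,
                       exons_per_gene = 3L,
                       intron_bp = 150L,
                       gene_gap_bp = 500L,
                       n_chroms = 10L) {
  stopifnot(metastatic_fraction >= 0, metastatic_fraction <= 1,
            lambda_nonmet >= 0, lambda_met >= 0, target_mb > 0,
            all(caller_sensitivity >= 0 & caller_sensitivity <= 1),
            artifact_detection >= 0, artifact_detection <= 1,
            cds_codons >= 20, exons_per_gene >= 1)
  structure(as.list(environment()), class = "cf_sim_config")
}

#' Downscaled simulation preserving the study's per-Mb composition
#'
#' Shrinks the simulated target (and with it every per-patient count that
#' scales with target size: germline SNPs, artifacts, position clusters,
#' caller false positives) by the same factor, so class proportions —
#' and therefore sensitivity/FDR expectations — match the full-size
#' conditions while the instance stays small. Rates per Mb and all
#' thresholds are untouched.
#'
#' @param seed Master seed.
#' @param n_patients Cohort size.
#' @param target_mb Downscaled target size in Mb.
#' @param ... Further overrides passed to [sim_config()].
#' @return A `cf_sim_config`.
#' @export
sim_config_scaled <- function(seed = 1L, n_patients = 10L, target_mb = 4,
                              ...) {
  f <- target_mb / 91.08
  base <- sim_config()
  scale_n <- function(x) {
    setNames(pmax(1L, as.integer(round(x * f))), names(x))
  }
  sim_config(
    seed = seed, n_patients = n_patients, target_mb = target_mb,
    germline_snps = scale_n(base$germline_snps),
    artifacts_per_patient = scale_n(base$artifacts_per_patient),
    n_position_clusters = scale_n(base$n_position_clusters),
    n_pon_sites = scale_n(base$n_pon_sites),
    caller_fp_per_patient = scale_n(base$caller_fp_per_patient),
    n_filler_genes = 30L, cds_codons = 3000L,
    ...
  )
}

BCAA_GENES <- c("HMGCS2", "AUH", "ACAT1", "ACADSB", "EHHADH")
HYPOXIA_GENES <- c("ARNT", "EPAS1", "PAK3", "RAF1", "TFE3")
NAMED_GENES <- c(
  "MUC19", "OBSCN", "KMT2D", "RYR1", "MUC16", "DNAH1", "PLEC", "DNHD1",
  "MACF1", "USH2A", "UBR4", "FAT4", "SYNE2", "LRP1", "LRP1B", "HECTD4",
  "INTS1", "SYNE1", "RYR3", "TTN", "DMD", "ATM", "DNAH11", "NBEAL1",
  "MYCBP2", BCAA_GENES, HYPOXIA_GENES
)

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * k) %% 2147483647)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_cds <- function(n_codons) {
  codons <- names(Biostrings::GENETIC_CODE)
  non_stop <- codons[Biostrings::GENETIC_CODE != "*"]
  body <- sample(setdiff(non_stop, "ATG") , n_codons - 2L, replace = TRUE)
  paste(c("ATG", body, "TAA"), collapse = "")
}

#' Build the synthetic genome
#'
#' Constructs gene models (alternating strands, `exons_per_gene` exons per
#' CDS, no internal stop codons), the reference sequences, the target BED
#' intervals (the exons), and the exonic position pool used for variant
#' placement. Deterministic given the config seed; build once and pass to
#' [simulate_cohort()] when running many replicates.
#'
#' @param config A [sim_config()].
#' @return A `cf_genome` list: `models`, `reference`, `targets`, `pool`
#'   (tibble `chrom`, `pos`, `gene`, `base`, `cds_pos`, `special`).
#' @export
build_genome <- function(config) {
  set.seed(derive_seed(config$seed, 1L))
  genes <- c(NAMED_GENES,
             sprintf("GENE%03d", seq_len(config$n_filler_genes)))
  special <- unique(c(BCAA_GENES, HYPOXIA_GENES, config$metastasis_gene,
                      "MUC16", "MUC19"))
  n_genes <- length(genes)
  per_chrom <- ceiling(n_genes / config$n_chroms)
  cds_len <- 3L * config$cds_codons
  exon_w <- diff(round(seq(0, cds_len, length.out =
                             config$exons_per_gene + 1L)))

  model_rows <- vector("list", n_genes)
  chrom_parts <- vector("list", config$n_chroms)
  for (i in seq_len(config$n_chroms)) chrom_parts[[i]] <- list()
  cursor <- rep(1L, config$n_chroms)

  for (gi in seq_len(n_genes)) {
    ci <- (gi - 1L) %/% per_chrom + 1L
    cc <- paste0("chr", ci)
    strand <- if (gi %% 2L == 0L) "-" else "+"
    cds <- random_cds(config$cds_codons)
    genomic_cds <- if (strand == "-") revcomp(cds) else cds
    # split the genomic-forward CDS across exons with introns between
    starts <- integer(config$exons_per_gene)
    ends <- integer(config$exons_per_gene)
    off <- 0L
    pos0 <- cursor[ci] + config$gene_gap_bp
    parts <- list(rand_dna(config$gene_gap_bp))
    for (e in seq_len(config$exons_per_gene)) {
      exon_seq <- substr(genomic_cds, off + 1L, off + exon_w[e])
      starts[e] <- pos0
      ends[e] <- pos0 + exon_w[e] - 1L
      parts <- c(parts, exon_seq)
      pos0 <- pos0 + exon_w[e]
      off <- off + exon_w[e]
      if (e < config$exons_per_gene) {
        parts <- c(parts, rand_dna(config$intron_bp))
        pos0 <- pos0 + config$intron_bp
      }
    }
    cursor[ci] <- pos0
    chrom_parts[[ci]] <- c(chrom_parts[[ci]], parts)
    model_rows[[gi]] <- tibble(
      gene = genes[gi], chrom = cc, strand = strand,
      start = starts, end = ends
    )
  }
  models <- bind_rows(model_rows)
  reference <- vapply(seq_len(config$n_chroms), function(ci) {
    paste(unlist(chrom_parts[[ci]]), collapse = "")
  }, character(1))
  names(reference) <- paste0("chr", seq_len(config$n_chroms))

  # exonic pool with CDS coordinates and reference bases
  pool_list <- models |>
    arrange(gene, start) |>
    group_by(gene) |>
    group_map(function(ex, g) {
      w <- ex$end - ex$start + 1L
      cum <- cumsum(c(0L, w[-length(w)]))
      pos <- unlist(mapply(seq.int, ex$start, ex$end, SIMPLIFY = FALSE))
      cds_fwd <- unlist(mapply(function(a, b, o) seq.int(o + 1L, o + b - a + 1L),
                               ex$start, ex$end, cum, SIMPLIFY = FALSE))
      L <- sum(w)
      cds_pos <- if (ex$strand[1] == "-") L - cds_fwd + 1L else cds_fwd
      tibble(chrom = ex$chrom[1], pos = pos, gene = g$gene,
             cds_pos = cds_pos)
    })
  pool <- bind_rows(pool_list)
  pool$base <- extract_bases(reference, pool$chrom, pool$pos)
  pool$special <- pool$gene %in% special
  targets <- target_regions(
    models |> transmute(chrom, start = start - 1L, end = end)
  )
  # precomputed placement indices (reused across simulation replicates)
  ns_idx <- which(!pool$special)
  mid_ok <- pool$cds_pos %% 3L == 2L & pool$cds_pos > 3L &
    pool$cds_pos < 3L * (config$cds_codons - 1L)
  index <- list(
    ns_idx = ns_idx,
    ns_cg = ns_idx[pool$base[ns_idx] %in% c("C", "G")],
    special_mid = split(which(mid_ok & pool$special),
                        pool$gene[mid_ok & pool$special]),
    blacklist_idx = which(pool$gene %in% c("MUC16", "MUC19"))
  )
  structure(list(models = models, reference = reference, targets = targets,
                 pool = pool, index = index),
            class = "cf_genome")
}

extract_bases <- function(reference, chrom, pos) {
  out <- character(length(pos))
  for (cc in unique(chrom)) {
    sel <- chrom == cc
    out[sel] <- strsplit(substring(reference[[cc]], 1L), "")[[1]][pos[sel]]
  }
  out
}

OTHER_BASES <- matrix(
  c("C", "G", "T",   # A
    "A", "G", "T",   # C
    "A", "C", "T",   # G
    "A", "C", "G"),  # T
  nrow = 4, byrow = TRUE, dimnames = list(c("A", "C", "G", "T"), NULL)
)

random_alt <- function(ref_base) {
  idx <- sample.int(3L, length(ref_base), replace = TRUE)
  OTHER_BASES[cbind(match(ref_base, rownames(OTHER_BASES)), idx)]
}

rtrunc_beta_ge <- function(n, shape1, shape2, lo) {
  u <- runif(n, pbeta(lo, shape1, shape2), 1)
  qbeta(u, shape1, shape2)
}

#' Simulate a complete synthetic study
#'
#' Draws the truth manifest (every variant that will appear in any emitted
#' VCF, labelled with its origin class), the clinical table with
#' burden-coupled metastasis and gene-set-coupled survival, the population
#' allele-frequency table and the panel-of-normals site list. Byte-stable
#' under the config seed.
#'
#' @param config A [sim_config()].
#' @param genome Optional prebuilt [build_genome()] result for the same
#'   config (the genome stream is seeded independently, so results are
#'   identical either way).
#' @return A `cf_cohort` list: `config`, `genome`, `manifest`, `clinical`,
#'   `af_table`, `pon_sites`.
#' @export
simulate_cohort <- function(config, genome = NULL) {
  if (is.null(genome)) genome <- build_genome(config)
  set.seed(derive_seed(config$seed, 2L))
  n <- config$n_patients
  patients <- sprintf("P%03d", seq_len(n))
  if (n == 0) {
    return(structure(list(config = config, genome = genome,
                          manifest = empty_manifest(),
                          clinical = validate_clinical(empty_clinical()),
                          af_table = tibble(chrom = character(),
                                            pos = integer(),
                                            ref = character(),
                                            alt = character(),
                                            af = double()),
                          pon_sites = character()),
                     class = "cf_cohort"))
  }
  n_met <- round(config$metastatic_fraction * n)
  metastatic <- seq_len(n) %in% sample.int(n, n_met)

  pool <- genome$pool
  ns_idx <- genome$index$ns_idx
  # oxoG artifacts live at reference C/G positions (C>A / G>T class);
  # designed gene hits sit at middle codon bases (always nonsynonymous)
  ns_cg <- genome$index$ns_cg
  special_mid <- genome$index$special_mid
  blacklist_idx <- genome$index$blacklist_idx

  # shared panel-of-normals loci
  pon_pool <- ns_idx[sample.int(length(ns_idx), config$n_pon_sites,
                                useHash = TRUE)]
  pon_alt <- random_alt(pool$base[pon_pool])
  pon_sites <- locus_key(pool$chrom[pon_pool], pool$pos[pon_pool],
                         pool$base[pon_pool], pon_alt)

  bcaa_mut <- runif(n) < config$bcaa_fraction
  hypoxia_mut <- runif(n) < config$hypoxia_fraction
  met_gene_mut <- metastatic | runif(n) < config$metastasis_gene_bg

  per_patient <- vector("list", n)
  for (i in seq_len(n)) {
    lam <- if (metastatic[i]) config$lambda_met else config$lambda_nonmet
    n_q <- rpois(1, lam * config$target_mb)
    # allocate part of the qualifying budget to designed gene-set hits
    special_genes <- character(0)
    if (bcaa_mut[i]) {
      special_genes <- c(special_genes,
                         sample(BCAA_GENES, min(5, 1 + rbinom(1, 2, 0.5))))
    }
    if (hypoxia_mut[i]) {
      special_genes <- c(special_genes,
                         sample(HYPOXIA_GENES, min(5, 1 + rbinom(1, 2, 0.5))))
    }
    if (met_gene_mut[i]) {
      special_genes <- c(special_genes, config$metastasis_gene)
    }
    sp_idx <- vapply(special_genes, function(g) {
      cand <- special_mid[[g]]
      cand[sample.int(length(cand), 1L)]
    }, integer(1))
    n_uniform <- max(n_q - length(sp_idx), 0L)
    n_sub <- rpois(1, config$lambda_subthreshold * config$target_mb)
    n_germ <- config$germline_snps
    art <- config$artifacts_per_patient
    n_clu <- config$n_position_clusters
    fp <- config$caller_fp_per_patient

    n_main <- n_uniform + n_sub + n_germ +
      sum(art[c("strand_bias", "cluster_mismatch", "low_support")]) +
      sum(fp)
    main_idx <- ns_idx[sample.int(length(ns_idx), n_main,
                                  useHash = TRUE)]
    origin <- rep(c("somatic", "somatic_lowvaf", "germline",
                    "strand_bias", "cluster_mismatch", "low_support",
                    paste0("caller_fp_", names(fp))),
                  c(n_uniform, n_sub, n_germ,
                    art[["strand_bias"]], art[["cluster_mismatch"]],
                    art[["low_support"]], fp))
    oxo_idx <- ns_cg[sample.int(length(ns_cg), art[["oxog"]],
                                useHash = TRUE)]
    idx <- c(main_idx, oxo_idx)
    origin <- c(origin, rep("oxog", art[["oxog"]]))
    # designed gene hits (qualifying somatics in the special genes)
    if (length(sp_idx)) {
      idx <- c(sp_idx, idx)
      origin <- c(rep("somatic", length(sp_idx)), origin)
    }
    # blacklist-gene false positives
    if (art[["blacklist_fp"]] > 0) {
      bl <- sample(blacklist_idx, art[["blacklist_fp"]])
      idx <- c(idx, bl)
      origin <- c(origin, rep("blacklist_fp", art[["blacklist_fp"]]))
    }
    # recurrent PoN loci
    pon_in <- which(runif(config$n_pon_sites) < config$pon_recurrence)
    # positional clusters: triplets spanning < 100 bp within one exon
    clu_idx <- integer(0)
    if (n_clu > 0) {
      anchors <- sample.int(length(ns_idx) - 61L, n_clu,
                            useHash = TRUE)
      for (a in anchors) {
        trip <- ns_idx[c(a, a + 30L, a + 60L)]
        same <- pool$chrom[trip[1]] == pool$chrom[trip[3]] &&
          pool$pos[trip[3]] - pool$pos[trip[1]] < 100L
        if (same) clu_idx <- c(clu_idx, trip)
      }
    }
    p_idx <- c(idx, pon_pool[pon_in], clu_idx)
    p_origin <- c(origin, rep("pon", length(pon_in)),
                  rep("clustered_site", length(clu_idx)))
    p_alt <- rep(NA_character_, length(p_idx))
    if (length(pon_in)) p_alt[p_origin == "pon"] <- pon_alt[pon_in]
    is_oxo <- p_origin == "oxog"
    p_alt[is_oxo] <- ifelse(pool$base[p_idx[is_oxo]] == "C", "A", "T")
    keep <- !duplicated(p_idx)
    per_patient[[i]] <- list(idx = p_idx[keep], origin = p_origin[keep],
                             alt_fixed = p_alt[keep])
  }
  idx_all <- unlist(lapply(per_patient, `[[`, "idx"))
  mf <- tibble(
    patient_id = rep(patients,
                     vapply(per_patient, function(x) length(x$idx),
                            integer(1))),
    origin = unlist(lapply(per_patient, `[[`, "origin")),
    chrom = pool$chrom[idx_all],
    pos = pool$pos[idx_all],
    gene = pool$gene[idx_all],
    ref = pool$base[idx_all]
  )
  alt_fixed <- unlist(lapply(per_patient, `[[`, "alt_fixed"))
  mf$alt <- ifelse(is.na(alt_fixed), random_alt(mf$ref), alt_fixed)

  # a small fraction of uniform somatics become indels
  ind <- which(mf$origin == "somatic" &
                 runif(nrow(mf)) < config$indel_fraction)
  if (length(ind)) {
    new_pos <- mf$pos[ind]; new_ref <- mf$ref[ind]; new_alt <- mf$alt[ind]
    for (k in seq_along(ind)) {
      m <- make_indel(mf$chrom[ind[k]], mf$pos[ind[k]], genome$reference)
      new_pos[k] <- m$pos; new_ref[k] <- m$ref; new_alt[k] <- m$alt
    }
    mf$pos[ind] <- new_pos; mf$ref[ind] <- new_ref; mf$alt[ind] <- new_alt
  }

  mf <- draw_read_evidence(mf, config)
  mf <- draw_caller_detection(mf, config)
  mf$key <- variant_key(mf$patient_id, mf$chrom, mf$pos, mf$ref, mf$alt)
  mf$metastatic <- metastatic[match(mf$patient_id, patients)]

  # population AF table: germline SNPs are common polymorphisms
  germ <- mf |>
    filter(origin == "germline") |>
    distinct(chrom, pos, ref, alt)
  af_table <- germ |> mutate(af = runif(n(), 0.02, 0.5))

  clinical <- draw_clinical(patients, metastatic,
                            bcaa_mut | hypoxia_mut, config)
  structure(
    list(config = config, genome = genome, manifest = mf,
         clinical = clinical, af_table = af_table,
         pon_sites = pon_sites,
         geneset_truth = tibble(patient_id = patients,
                                bcaa = bcaa_mut, hypoxia = hypoxia_mut,
                                metastatic = metastatic)),
    class = "cf_cohort"
  )
}

make_indel <- function(chrom, pos, reference) {
  len <- sample.int(3L, 1L)
  anchor <- substr(reference[[chrom]], pos, pos)
  if (runif(1) < 0.5) {  # insertion
    ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
    ref <- anchor
    alt <- paste0(anchor, ins)
  } else {               # deletion
    ref <- substr(reference[[chrom]], pos, pos + len)
    alt <- anchor
  }
  n <- normalize_one(chrom, pos, ref, alt,
                     setNames(list(reference[[chrom]]), chrom))
  tibble(pos = n$pos, ref = n$ref, alt = n$alt)
}

draw_read_evidence <- function(mf, config) {
  n <- nrow(mf)
  depth <- pmax(rpois(n, config$depth_mean), 30L)
  ndepth <- pmax(rpois(n, config$depth_mean), 30L)
  vaf <- rtrunc_beta_ge(n, config$vaf_shape1, config$vaf_shape2, 0.05)
  alt_n <- pmax(rbinom(n, depth, vaf), ceiling(0.05 * depth))
  normal_alt <- pmin(rbinom(n, ndepth, 0.002), 2L)

  o <- mf$origin
  sub <- which(o == "somatic_lowvaf")
  if (length(sub)) {
    v <- runif(length(sub), 0.02, 0.0499)
    cap <- ceiling(0.05 * depth[sub]) - 1L
    alt_n[sub] <- pmin(pmax(rbinom(length(sub), depth[sub], v), 1L), cap)
  }
  germ <- which(o == "germline")
  if (length(germ)) {
    v <- rbeta(length(germ), 30, 30)
    alt_n[germ] <- pmax(rbinom(length(germ), depth[germ], v), 4L)
    normal_alt[germ] <- pmax(rbinom(length(germ), ndepth[germ], v), 4L)
  }
  low <- which(o == "low_support")
  if (length(low)) {
    sub_a <- runif(length(low)) < 0.6
    alt_n[low][sub_a] <- sample(1:2, sum(sub_a), replace = TRUE)
    normal_alt[low][!sub_a] <- sample(4:8, sum(!sub_a), replace = TRUE)
  }
  cfp <- which(startsWith(o, "caller_fp"))
  if (length(cfp)) {
    alt_n[cfp] <- sample(1:3, length(cfp), replace = TRUE)
  }
  oxo <- which(o == "oxog")
  alt_n[oxo] <- pmax(alt_n[oxo], 4L)

  # strand split of alt reads (balanced unless strand-biased)
  alt_fwd <- rbinom(n, alt_n, 0.5)
  sb <- which(o == "strand_bias")
  alt_fwd[sb] <- alt_n[sb]
  ref_n <- depth - alt_n
  ref_fwd <- rbinom(n, ref_n, 0.5)

  # read-pair orientation: balanced for real variants; 8-oxoG damage
  # strikes one strand of the template molecule, so artifact-supporting
  # reads share one orientation up to rare stray reads
  f1r2 <- rbinom(n, alt_n, 0.5)
  if (length(oxo)) {
    f1r2[oxo] <- alt_n[oxo] - rbinom(length(oxo), alt_n[oxo], 0.005)
  }

  mf$tumor_depth <- as.integer(depth)
  mf$tumor_alt <- as.integer(alt_n)
  mf$normal_depth <- as.integer(ndepth)
  mf$normal_alt <- as.integer(normal_alt)
  mf$alt_fwd <- as.integer(alt_fwd)
  mf$alt_rev <- as.integer(alt_n - alt_fwd)
  mf$ref_fwd <- as.integer(ref_fwd)
  mf$ref_rev <- as.integer(ref_n - ref_fwd)
  mf$f1r2 <- as.integer(f1r2)
  mf$f2r1 <- as.integer(alt_n - f1r2)
  mf$vaf <- mf$tumor_alt / mf$tumor_depth
  mf
}

draw_caller_detection <- function(mf, config) {
  n <- nrow(mf)
  for (caller in CALLERS) {
    p <- ifelse(
      mf$origin %in% c("somatic", "somatic_lowvaf", "germline"),
      config$caller_sensitivity[[caller]],
      config$artifact_detection
    )
    fp_of_caller <- mf$origin == paste0("caller_fp_", caller)
    other_fp <- startsWith(mf$origin, "caller_fp") & !fp_of_caller
    called <- runif(n) < p
    called[fp_of_caller] <- TRUE
    called[other_fp] <- FALSE
    # oxoG needs Mutect2's orientation counts to be filterable: damage
    # artifacts are systematically recalled
    mf[[paste0("called_", caller)]] <- called
  }
  mf
}

draw_clinical <- function(patients, metastatic, geneset_mut, config) {
  n <- length(patients)
  minority <- function(k, force_true = NULL) {
    # logical vector with exactly k TRUE, optionally containing force_true
    out <- rep(FALSE, n)
    pick <- if (is.null(force_true)) sample.int(n, min(k, n)) else {
      base <- which(force_true)
      extra <- setdiff(sample.int(n, n), base)
      c(base, extra)[seq_len(min(max(k, length(base)), n))]
    }
    out[pick] <- TRUE
    out
  }
  frac <- function(p) max(1L, round(p * n))
  female <- minority(frac(2 / 50))
  t13 <- minority(frac(13 / 50))
  n0 <- minority(frac(28 / 50))
  stage_iv <- minority(frac(39 / 50), force_true = metastatic)
  pni <- minority(frac(17 / 50))
  lvi <- minority(frac(11 / 50))
  p16 <- minority(frac(4 / 50))
  age <- pmin(pmax(round(rnorm(n, 60, 10)), 30), 90)

  hazard <- config$baseline_hazard *
    ifelse(geneset_mut, config$geneset_hr, 1)
  death <- rexp(n, hazard)
  censor <- runif(n, config$censor_range[1], config$censor_range[2])
  validate_clinical(tibble(
    patient_id = patients,
    age = age,
    sex = ifelse(female, "Female", "Male"),
    t_stage = ifelse(t13, "T1-3", "T4"),
    n_stage = ifelse(n0, "N0", "N+"),
    clinical_stage = ifelse(stage_iv, "IV", "I-III"),
    metastasis = metastatic,
    perineural_invasion = pni,
    lymphovascular_invasion = lvi,
    p16 = p16,
    os_time = round(pmin(death, censor)),
    event = death <= censor
  ))
}

empty_manifest <- function() {
  tibble(patient_id = character(), origin = character(),
         chrom = character(), pos = integer(), gene = character(),
         ref = character(), alt = character(), key = character())
}

empty_clinical <- function() {
  tibble(patient_id = character(), age = double(), sex = character(),
         t_stage = character(), n_stage = character(),
         clinical_stage = character(), metastasis = logical(),
         perineural_invasion = logical(),
         lymphovascular_invasion = logical(), p16 = logical(),
         os_time = double(), event = logical())
}

#' @exportS3Method base::print
print.cf_cohort <- function(x, ...) {
  cat(sprintf("<cf_cohort> %d patients, %d manifest variants (%d somatic)\n",
              nrow(x$clinical), nrow(x$manifest),
              sum(x$manifest$origin == "somatic")))
  invisible(x)
}
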