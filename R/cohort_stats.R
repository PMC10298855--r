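#' Plasma mutation burden (PMB)
#'
#' PMB is the number of somatic mutations with a cfDNA VAF of at least
#' `min_vaf` (default 5%) inside the capture target region, divided by the
#' target size in megabases (default the 91.08 Mb whole-exome+UTR design).
#' When the annotated `consequence` column is present, per-type counts of
#' the qualifying mutations are included.
#'
#' @param variants Kept (post-cascade) variant tibble with `sample_id`,
#'   `chrom`, `pos`, `vaf` and optionally `consequence`.
#' @param targets A `cf_targets` object ([read_target_regions()]); its
#'   `total_mb` is the denominator. Defaults to the universal 91.08 Mb
#'   target.
#' @param min_vaf Qualifying VAF threshold (inclusive; default 0.05).
#' @param patients Character vector of all patient IDs, so patients with
#'   zero qualifying mutations keep a row.
#' @param target_mb Optional denominator override in Mb: membership is
#'   still tested against `targets`, but the burden is expressed per Mb
#'   of this size (useful when intervals cover a downscaled exome whose
#'   rates are defined against a larger design).
#' @return Tibble: `patient_id`, `qualifying`, `pmb`, and per-consequence
#'   count columns (`n_synonymous`, ...) when consequences are annotated.
#' @export
compute_pmb <- function(variants, targets = read_target_regions(),
                        min_vaf = 0.05, patients = NULL,
                        target_mb = NULL) {
  mb <- target_mb %||% cfsomatic::target_mb(targets)
  if (is.null(mb) || !is.finite(mb) || mb <= 0) {
    abort("target size is zero: refusing to divide (supply a non-empty target region)")
  }
  variants <- as_tibble(variants)
  qual <- variants |>
    filter(!is.na(vaf), vaf >= min_vaf,
           in_targets(targets, chrom, pos))
  if (is.null(patients)) patients <- sort(unique(variants$sample_id))
  out <- tibble(patient_id = patients) |>
    left_join(count(qual, sample_id, name = "qualifying"),
              by = c(patient_id = "sample_id")) |>
    mutate(qualifying = ifelse(is.na(qualifying), 0L, qualifying),
           pmb = qualifying / mb)
  if ("consequence" %in% names(qual) && nrow(qual) > 0 &&
      !all(is.na(qual$consequence))) {
    type_counts <- qual |>
      count(sample_id, consequence) |>
      mutate(consequence = factor(consequence,
                                  levels = CONSEQUENCE_TYPES)) |>
      tidyr::complete(sample_id, consequence, fill = list(n = 0L)) |>
      tidyr::pivot_wider(names_from = consequence, values_from = n,
                         names_prefix = "n_")
    out <- left_join(out, type_counts, by = c(patient_id = "sample_id"))
    for (col in paste0("n_", CONSEQUENCE_TYPES)) {
      if (!col %in% names(out)) out[[col]] <- 0L
      out[[col]][is.na(out[[col]])] <- 0L
    }
  }
  out
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two groups. Uses exact enumeration of
#' the U distribution when the combined sample size is at most 12 and
#' there are no ties, otherwise the normal approximation with tie
#' correction (no continuity correction), the appropriate regime for
#' cohort-scale data.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @return Tibble with `u` (number of (x, y) pairs with x > y, ties
#'   counted half), `p_value`, `method`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (length(x) + length(y)) <= 12
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = FALSE)
  )
  tibble(u = unname(ht$statistic), p_value = ht$p.value,
         method = if (exact) "exact" else "normal approximation")
}

#' Tie-corrected Spearman rank correlation
#'
#' Pearson correlation of mid-ranks with the t-distribution approximation
#' for the p-value.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Tibble with `rho`, `p_value`.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("need two equal-length vectors of length >= 3")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined for a constant vector")
  }
  ht <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble(rho = unname(ht$estimate), p_value = ht$p.value)
}

#' Chi-square / Fisher routing for 2x2 tables
#'
#' Pearson chi-square without continuity correction, switching to the
#' two-sided Fisher exact test whenever any expected cell count is 5 or
#' less (the small-sample rule, applied boundary-inclusively so the exact
#' test covers the marginal case).
#'
#' @param table A 2x2 matrix of nonnegative counts.
#' @return Tibble with `p_value`, `method`, `statistic` (chi-square
#'   statistic, `NA` for Fisher).
#' @export
categorical_test <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  n <- sum(table)
  if (n == 0) abort("all-zero table")
  expected <- outer(rowSums(table), colSums(table)) / n
  if (any(expected <= 5)) {
    ht <- fisher.test(table)
    tibble(p_value = ht$p.value, method = "fisher",
           statistic = NA_real_)
  } else {
    ht <- suppressWarnings(chisq.test(table, correct = FALSE))
    tibble(p_value = ht$p.value, method = "chi-square",
           statistic = unname(ht$statistic))
  }
}

#' Age-adjusted linear model for burden
#'
#' Ordinary least squares of the burden outcome on a binary clinical
#' predictor with age as covariate, all variables standardized, so the
#' reported `B` is the standardized regression coefficient of the
#' predictor.
#'
#' @param y Numeric outcome (e.g. per-patient PMB).
#' @param predictor Binary (logical/0-1) clinical predictor.
#' @param covariate Numeric covariate (age in years).
#' @return Tibble with `B` (standardized coefficient of the predictor) and
#'   `p_value`; the fitted `lm` is attached as attribute `"model"`.
#' @export
adjusted_linear_model <- function(y, predictor, covariate) {
  if (length(y) <= 3) abort("need n > 3")
  predictor <- as.numeric(predictor)
  df <- tibble(y = as.numeric(scale(y)),
               predictor = as.numeric(scale(predictor)))
  if (sd(covariate) == 0) {
    # degenerate covariate: reduces to the two-group model
    fit <- lm(y ~ predictor, data = df)
  } else {
    df$covariate <- as.numeric(scale(covariate))
    fit <- lm(y ~ predictor + covariate, data = df)
  }
  cf <- summary(fit)$coefficients
  if (anyNA(coef(fit))) abort("collinear inputs: model is singular")
  out <- tibble(B = cf["predictor", "Estimate"],
                p_value = cf["predictor", "Pr(>|t|)"])
  attr(out, "model") <- fit
  out
}

#' Bonferroni-adjusted significance threshold
#'
#' `alpha / m`, rounded to `digits` decimals for display (the convention
#' used in the clinical tables: 0.05/9 is reported as 0.006, 0.05/2 as
#' 0.025). Pass `digits = NULL` for the exact threshold.
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param m Number of tests in the family (>= 1).
#' @param digits Decimal places for display rounding (default 3).
#' @return The adjusted threshold.
#' @export
bonferroni_alpha <- function(alpha = 0.05, m, digits = 3) {
  if (m < 1) abort("m must be >= 1")
  out <- alpha / m
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Burden vs clinical dichotomies
#'
#' Mann-Whitney comparison of a per-patient burden measure across every
#' clinical dichotomy (age group, sex, T stage, N stage, clinical stage,
#' metastasis, perineural and lymphovascular invasion, p16), with group
#' summaries and the family-wise Bonferroni threshold.
#'
#' @param burden Tibble with `patient_id` and the burden column.
#' @param clinical Validated clinical tibble ([read_clinical_table()]).
#' @param value Burden column name (default `"pmb"`).
#' @param parameters Clinical dichotomy columns to test.
#' @param alpha Family-wise error rate (default 0.05).
#' @return Tibble: one row per parameter with group ns, means, SDs,
#'   `p_value`, `bonferroni_alpha`, `significant`.
#' @export
burden_clinical_table <- function(burden, clinical, value = "pmb",
                                  parameters = c("age_group", "sex",
                                                 "t_stage", "n_stage",
                                                 "clinical_stage",
                                                 "metastasis",
                                                 "perineural_invasion",
                                                 "lymphovascular_invasion",
                                                 "p16"),
                                  alpha = 0.05) {
  dat <- inner_join(burden, clinical, by = "patient_id")
  thr <- bonferroni_alpha(alpha, length(parameters))
  rows <- lapply(parameters, function(p) {
    g <- dichotomy_groups(dat[[p]])
    v <- dat[[value]]
    if (!any(g$in_b) || !any(!g$in_b)) {
      abort(sprintf("clinical dichotomy '%s' has an empty group", p))
    }
    mw <- mann_whitney(v[!g$in_b], v[g$in_b])
    tibble(parameter = p,
           group_a = g$labels[1], n_a = sum(!g$in_b),
           mean_a = mean(v[!g$in_b]), sd_a = sd(v[!g$in_b]),
           group_b = g$labels[2], n_b = sum(g$in_b),
           mean_b = mean(v[g$in_b]), sd_b = sd(v[g$in_b]),
           p_value = mw$p_value)
  })
  bind_rows(rows) |>
    mutate(bonferroni_alpha = thr, significant = p_value < thr)
}

dichotomy_groups <- function(x) {
  if (is.logical(x)) {
    list(in_b = x, labels = c("No", "Yes"))
  } else {
    lv <- sort(unique(x))
    if (length(lv) != 2) abort("clinical parameter is not a dichotomy")
    list(in_b = x == lv[2], labels = lv)
  }
}

#' Mutation-type burden by clinical dichotomy
#'
#' Per-consequence-type mean and SD of qualifying mutation counts in each
#' clinical group, with a Mann-Whitney p-value per type.
#'
#' @param burden [compute_pmb()] output carrying the per-type `n_*`
#'   columns.
#' @param clinical Validated clinical tibble.
#' @param parameter Clinical dichotomy column (default `"metastasis"`).
#' @param alpha Family-wise error rate over the nine types.
#' @return Tibble: `mutation_type`, group means/SDs, `p_value`,
#'   `bonferroni_alpha`, `significant`.
#' @export
mutation_type_table <- function(burden, clinical,
                                parameter = "metastasis", alpha = 0.05) {
  type_cols <- paste0("n_", CONSEQUENCE_TYPES)
  missing_cols <- setdiff(type_cols, names(burden))
  if (length(missing_cols)) {
    abort("burden table lacks per-type counts; annotate consequences first")
  }
  dat <- inner_join(burden, clinical, by = "patient_id")
  g <- dichotomy_groups(dat[[parameter]])
  if (!any(g$in_b) || !any(!g$in_b)) abort("empty clinical group")
  thr <- bonferroni_alpha(alpha, length(type_cols))
  rows <- lapply(type_cols, function(col) {
    v <- dat[[col]]
    tibble(mutation_type = sub("^n_", "", col),
           group_a = g$labels[1], mean_a = mean(v[!g$in_b]),
           sd_a = sd(v[!g$in_b]),
           group_b = g$labels[2], mean_b = mean(v[g$in_b]),
           sd_b = sd(v[g$in_b]),
           p_value = mann_whitney(v[!g$in_b], v[g$in_b])$p_value)
  })
  bind_rows(rows) |>
    mutate(bonferroni_alpha = thr, significant = p_value < thr)
}

#' Per-gene association with a clinical dichotomy
#'
#' For each gene column of the mutation matrix, tests the 2x2 table of
#' mutation presence against the clinical dichotomy (chi-square/Fisher
#' routing), Bonferroni-corrected over the number of genes tested.
#'
#' @param matrix A [build_gene_matrix()] result.
#' @param clinical Validated clinical tibble.
#' @param parameter Clinical dichotomy column (default `"metastasis"`).
#' @param alpha Family-wise error rate.
#' @return Tibble: `gene`, `n_mutated`, `p_value`, `method`,
#'   `bonferroni_alpha`, `significant`.
#' @export
gene_clinical_association <- function(matrix, clinical,
                                      parameter = "metastasis",
                                      alpha = 0.05) {
  dat <- inner_join(as_tibble(matrix), clinical, by = "patient_id")
  genes <- setdiff(names(matrix), "patient_id")
  g <- dichotomy_groups(dat[[parameter]])
  thr <- bonferroni_alpha(alpha, length(genes), digits = NULL)
  rows <- lapply(genes, function(gn) {
    mut <- dat[[gn]]
    tab <- matrix(c(sum(!mut & !g$in_b), sum(!mut & g$in_b),
                    sum(mut & !g$in_b), sum(mut & g$in_b)),
                  nrow = 2, byrow = TRUE)
    ct <- categorical_test(tab)
    tibble(gene = gn, n_mutated = sum(mut), p_value = ct$p_value,
           method = ct$method)
  })
  bind_rows(rows) |>
    mutate(bonferroni_alpha = thr, significant = p_value < thr) |>
    arrange(p_value)
}

#' Per-patient gene-set mutation status
#'
#' A patient is gene-set positive when at least one member gene carries a
#' nonsynonymous mutation. Member genes absent from the matrix are ignored
#' with a warning; a gene set with no member in the matrix is an error.
#'
#' @param matrix A [build_gene_matrix()] result.
#' @param geneset Character vector of member gene symbols (non-empty).
#' @param name Optional gene-set name for reporting.
#' @return Tibble `patient_id`, `mutated`; the mutated fraction is
#'   attached as attribute `"fraction"`.
#' @export
geneset_status <- function(matrix, geneset, name = NULL) {
  stopifnot(length(geneset) > 0)
  present <- intersect(geneset, names(matrix))
  absent <- setdiff(geneset, names(matrix))
  if (length(absent)) {
    warn(paste("gene-set members absent from matrix:",
               paste(absent, collapse = ", ")))
  }
  if (length(present) == 0) abort("gene set empty after intersection with matrix")
  status <- Reduce(`|`, lapply(present, function(g) matrix[[g]]))
  out <- tibble(patient_id = matrix$patient_id, mutated = status)
  attr(out, "fraction") <- mean(status)
  attr(out, "name") <- name
  out
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per group and the 1-df log-rank
#' chi-square comparing them.
#'
#' @param data Data frame with time, event and group columns.
#' @param time,event,group Column names (tidy-eval) of follow-up time,
#'   event indicator (TRUE/1 = death) and the two-level group.
#' @return A `cf_km` object; `tidy()` gives the stepwise curves, `glance()`
#'   the log-rank chi-square and p-value, `autoplot()` the KM plot.
#' @export
km_logrank <- function(data, time = os_time, event = event,
                       group = mutated) {
  time <- pull(data, {{ time }})
  evt <- as.integer(pull(data, {{ event }}))
  grp <- pull(data, {{ group }})
  if (length(unique(grp)) != 2 || any(table(grp) < 1)) {
    abort("need exactly two non-empty groups")
  }
  df <- data.frame(time = time, event = evt, group = as.factor(grp))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  structure(
    list(fit = fit, chisq = unname(sd_$chisq),
         p_value = pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
         data = df),
    class = "cf_km"
  )
}

#' @exportS3Method base::print
print.cf_km <- function(x, ...) {
  cat(sprintf("<cf_km> log-rank chi-square = %.3f, p = %.4g\n",
              x$chisq, x$p_value))
  invisible(x)
}

#' @export
tidy.cf_km <- function(x, ...) {
  s <- summary(x$fit, censored = TRUE)
  tibble(
    time = s$time,
    n_risk = s$n.risk,
    n_event = s$n.event,
    surv = s$surv,
    group = sub("^group=", "", as.character(s$strata))
  )
}

#' @export
glance.cf_km <- function(x, ...) {
  tibble(chisq = x$chisq, df = 1L, p_value = x$p_value)
}

#' Two-sample power and required sample size
#'
#' Normal-approximation power of the two-sided two-sample comparison of
#' means at the pooled standardized difference, and the total sample size
#' required for a target power under the given allocation ratio.
#'
#' @param mean1,sd1,n1 Summary of group 1.
#' @param mean2,sd2,n2 Summary of group 2.
#' @param alpha Two-sided significance level (default 0.05).
#' @param target_power Power to solve the sample size for (default 0.8).
#' @param allocation_ratio n2/n1 used when solving for N (defaults to the
#'   observed ratio).
#' @return Tibble with `effect_size` (pooled standardized difference),
#'   `power` at the stated n, and `n_total_required` for the target power
#'   (`Inf` with a warning when the effect is zero).
#' @export
power_sample_size <- function(mean1, sd1, n1, mean2, sd2, n2,
                              alpha = 0.05, target_power = 0.8,
                              allocation_ratio = n2 / n1) {
  stopifnot(sd1 > 0, sd2 > 0, n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  d <- abs(mean1 - mean2) / sp
  za <- qnorm(1 - alpha / 2)
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  power <- pnorm(ncp - za) + pnorm(-ncp - za)  # both rejection tails
  if (d == 0) {
    warn("zero effect size: required sample size is infinite")
    n_req <- Inf
  } else {
    r <- allocation_ratio
    zb <- qnorm(target_power)
    n1_req <- (1 + 1 / r) * (za + zb)^2 / d^2
    n_req <- ceiling(n1_req) + ceiling(r * n1_req)
  }
  tibble(effect_size = d, power = power, n_total_required = n_req)
}
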