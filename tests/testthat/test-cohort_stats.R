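test_that("PMB divides qualifying in-target mutations by the target size", {
  v <- dplyr::bind_rows(lapply(1:9108, function(i)
    merged_row(pos = 10L * i, tumor_alt = 8L, tumor_depth = 80L)))
  b <- compute_pmb(v)
  expect_equal(b$pmb, 9108 / 91.08)   # = 100 mutations/Mb
  expect_equal(b$qualifying, 9108L)
  # no qualifying variants -> zero burden, patient row retained
  empty <- compute_pmb(v[0, ], patients = "S1")
  expect_equal(empty$pmb, 0)
  # sub-threshold VAF and off-target positions are excluded
  v2 <- dplyr::bind_rows(
    merged_row(pos = 50L, tumor_alt = 8L, tumor_depth = 80L),   # in
    merged_row(pos = 50000L, tumor_alt = 8L, tumor_depth = 80L),# out
    merged_row(pos = 60L, tumor_alt = 3L, tumor_depth = 80L)    # low VAF
  )
  tr <- target_regions(tibble::tibble(chrom = "chr1", start = 0L,
                                      end = 1000L))
  expect_equal(compute_pmb(v2, tr)$qualifying, 1L)
  # VAF exactly at the threshold qualifies
  v3 <- merged_row(tumor_alt = 4L, tumor_depth = 80L)
  expect_equal(compute_pmb(v3)$qualifying, 1L)
})

test_that("PMB is scale-consistent and refuses an empty target", {
  v <- dplyr::bind_rows(lapply(1:100, function(i)
    merged_row(pos = 100L * i, tumor_alt = 10L)))
  one <- compute_pmb(v, target_regions(
    tibble::tibble(chrom = "chr1", start = 0L, end = 100000L)))
  two <- compute_pmb(v, target_regions(
    tibble::tibble(chrom = c("chr1", "chr9"), start = 0L,
                   end = c(100000L, 100000L))))
  expect_equal(one$pmb, 2 * two$pmb)
  empty <- structure(tibble::tibble(chrom = character(), start = integer(),
                                    end = integer()),
                     total_mb = 0, universal = FALSE,
                     class = c("cf_targets", "tbl_df", "tbl", "data.frame"))
  expect_error(compute_pmb(v, empty), "refusing to divide")
})

test_that("Mann-Whitney separates, enumerates exactly at small n, and ranks", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$u, 0)
  expect_equal(mw$method, "exact")
  # exact branch equals the U-distribution recursion for n <= 6
  count_u <- function(m, n, u) {
    # number of arrangements with U statistic u (classical recursion)
    if (u < 0 || u > m * n) return(0)
    if (m == 0 || n == 0) return(as.numeric(u == 0))
    count_u(m - 1, n, u - n) + count_u(m, n - 1, u)
  }
  set.seed(4)
  x <- sample(1:1000, 5); y <- sample(2000:3000, 4)
  got <- mann_whitney(x, y)
  u_obs <- got$u
  total <- choose(9, 5)
  u_max <- 5 * 4
  probs <- vapply(0:u_max, function(u) count_u(5, 4, u), double(1)) / total
  p_oracle <- min(1, 2 * min(sum(probs[seq_len(u_obs + 1)]),
                             sum(probs[(u_obs + 1):(u_max + 1)])))
  expect_equal(got$p_value, p_oracle, tolerance = 1e-10)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Spearman rho is monotone-invariant and errors on constants", {
  set.seed(8)
  x <- rnorm(30); y <- x + rnorm(30)
  r1 <- spearman_corr(x, y)
  r2 <- spearman_corr(exp(x), y^3 + y)   # strictly monotone transforms
  expect_equal(r1$rho, r2$rho)
  expect_equal(spearman_corr(1:10, 1:10)$rho, 1.0)
  expect_error(spearman_corr(rep(1, 5), 1:5), "constant")
})

test_that("categorical test routes by expected counts and matches enumeration", {
  # all-or-nothing 10/10 table: exact hypergeometric enumeration
  tab <- matrix(c(10, 0, 0, 10), nrow = 2, byrow = TRUE)
  res <- categorical_test(tab)
  expect_equal(res$method, "fisher")
  p_oracle <- sum(vapply(0:10, function(k) {
    p <- stats::dhyper(k, 10, 10, 10)
    if (p <= stats::dhyper(10, 10, 10, 10) + 1e-12) p else 0
  }, double(1)))
  expect_equal(res$p_value, p_oracle, tolerance = 1e-10)
  expect_lt(res$p_value, 0.001)
  # balanced table: no association
  expect_equal(categorical_test(matrix(25, 2, 2))$p_value, 1.0)
  expect_equal(categorical_test(matrix(25, 2, 2))$method, "chi-square")
  # min expected < 5 routes to Fisher
  expect_equal(categorical_test(matrix(c(2, 8, 3, 7), 2, byrow = TRUE))$method,
               "fisher")
  expect_error(categorical_test(matrix(0, 2, 2)), "all-zero")
})

test_that("age-adjusted model recovers planted effects and degenerates sanely", {
  set.seed(12)
  n <- 200
  predictor <- rbinom(n, 1, 0.3)
  age <- rnorm(n, 60, 10)
  # planted standardized effect
  y <- 0.5 * predictor + 0.02 * age + rnorm(n)
  fit <- adjusted_linear_model(y, predictor, age)
  b_expected <- 0.5 * sd(predictor) / sd(y)
  expect_lt(abs(fit$B - b_expected), 2 * 0.07)
  expect_lt(fit$p_value, 0.01)
  # identical covariate reduces to the two-group standardized difference
  fit0 <- adjusted_linear_model(y, predictor, rep(60, n))
  fit_plain <- lm(scale(y) ~ scale(predictor))
  expect_equal(fit0$B, unname(coef(fit_plain)[2]))
  # null predictor is centered at zero over replications
  bs <- replicate(200, {
    yy <- rnorm(50)
    adjusted_linear_model(yy, rbinom(50, 1, 0.5), rnorm(50, 60, 5))$B
  })
  expect_lt(abs(mean(bs)), 0.05)
  expect_error(adjusted_linear_model(y, predictor, predictor), "singular")
})

test_that("Bonferroni thresholds reproduce the family footnotes", {
  expect_equal(bonferroni_alpha(0.05, 9), 0.006)
  expect_equal(bonferroni_alpha(0.05, 2), 0.025)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 9, digits = NULL), 0.05 / 9)
  expect_error(bonferroni_alpha(0.05, 0), "m must be")
})

test_that("burden and mutation-type tables test every clinical dichotomy", {
  co <- small_cohort()
  mf <- co$manifest[co$manifest$origin == "somatic", ]
  burden <- compute_pmb(
    dplyr::mutate(mf, sample_id = patient_id),
    target_regions(tibble::as_tibble(co$genome$targets)),
    patients = co$clinical$patient_id
  )
  tab <- burden_clinical_table(burden, co$clinical)
  expect_equal(nrow(tab), 9)
  expect_equal(unique(tab$bonferroni_alpha), 0.006)
  expect_equal(tab$n_a + tab$n_b, rep(nrow(co$clinical), 9))
  met <- tab[tab$parameter == "metastasis", ]
  expect_gt(met$mean_b, met$mean_a)  # metastatic group carries more burden
  expect_lt(met$p_value, 0.05)  # 2 vs 8 separation: exact p = 2/45

  kept <- classify_consequences(mf, co$genome$models, co$genome$reference)
  kept$sample_id <- kept$patient_id
  kept$vaf <- 0.2
  b2 <- compute_pmb(kept, patients = co$clinical$patient_id)
  tt <- mutation_type_table(b2, co$clinical, "metastasis")
  expect_equal(nrow(tt), 9)
  expect_setequal(tt$mutation_type, cfsomatic:::CONSEQUENCE_TYPES)
  # identical counts give zero spread
  b3 <- b2
  for (col in paste0("n_", cfsomatic:::CONSEQUENCE_TYPES)) b3[[col]] <- 5L
  t3 <- mutation_type_table(b3, co$clinical, "metastasis")
  expect_true(all(t3$sd_a == 0 & t3$sd_b == 0))
})

test_that("per-gene association flags the planted metastasis gene", {
  co <- small_cohort()
  res <- run_scaled_pipeline(co)
  kept <- classify_consequences(res$cascade$kept, co$genome$models,
                                co$genome$reference)
  mat <- build_gene_matrix(kept, patients = co$clinical$patient_id)
  assoc <- gene_clinical_association(mat, co$clinical, "metastasis")
  planted <- co$config$metastasis_gene
  expect_equal(assoc$gene[1], planted)
  expect_true(assoc$p_value[assoc$gene == planted] <
                min(assoc$p_value[assoc$gene != planted]))
  # extreme 2x2: a gene mutated in all metastatic, no others
  extreme <- tibble::tibble(patient_id = co$clinical$patient_id)
  extreme$XGENE <- co$clinical$metastasis
  class(extreme) <- class(mat)
  a2 <- gene_clinical_association(extreme, co$clinical, "metastasis")
  expect_lt(a2$p_value, 0.05)
})

test_that("gene-set status is the union of member columns", {
  m <- tibble::tibble(patient_id = paste0("P", 1:5),
                      A = c(TRUE, FALSE, FALSE, TRUE, FALSE),
                      B = c(FALSE, FALSE, TRUE, TRUE, FALSE))
  gs <- geneset_status(m, c("A", "B"))
  oracle <- m$A | m$B
  expect_equal(gs$mutated, oracle)
  expect_equal(attr(gs, "fraction"), mean(oracle))
  # 12 of 50 mutated reports 24%
  m2 <- tibble::tibble(patient_id = paste0("P", 1:50),
                       G = c(rep(TRUE, 12), rep(FALSE, 38)))
  expect_equal(attr(geneset_status(m2, "G"), "fraction"), 0.24)
  expect_warning(gs3 <- geneset_status(m, c("A", "ZZZ")), "absent")
  expect_equal(gs3$mutated, m$A)
  expect_error(suppressWarnings(geneset_status(m, "ZZZ")), "empty")
})

test_that("Kaplan-Meier equals the empirical survival without censoring", {
  times <- c(5, 8, 8, 12, 20, 33, 40, 41)
  grp <- rep(c("a", "b"), 4)
  km <- km_logrank(tibble::tibble(os_time = times, event = TRUE,
                                  mutated = grp))
  curves <- tidy(km)
  for (g in c("a", "b")) {
    tg <- sort(times[grp == g])
    cg <- curves[curves$group == g, ]
    emp <- vapply(cg$time, function(t) mean(tg > t), double(1))
    expect_equal(cg$surv, emp)
  }
})

test_that("log-rank statistic matches a hand-computed toy and the null", {
  # all events in group A before any in B
  d <- tibble::tibble(os_time = c(1, 2, 3, 10, 11, 12),
                      event = TRUE,
                      mutated = rep(c(TRUE, FALSE), each = 3))
  km <- km_logrank(d)
  # hand computation: at each of the first three deaths the expected
  # number of deaths in A is n_A/(n_A+n_B); O-E accumulates
  o_minus_e <- (1 - 3 / 6) + (1 - 2 / 5) + (1 - 1 / 4)
  v <- (3 * 3 / 6^2) + (2 * 3 / 5^2) + (1 * 3 / 4^2)
  expect_equal(km$chisq, o_minus_e^2 / v, tolerance = 1e-10)
  # identical groups: statistic 0, p 1
  d2 <- tibble::tibble(os_time = rep(c(3, 6, 9), 2), event = TRUE,
                       mutated = rep(c(TRUE, FALSE), 3))
  km2 <- km_logrank(d2)
  expect_lt(km2$chisq, 1e-10)
  expect_equal(km2$p_value, 1)
  expect_error(km_logrank(d2[d2$mutated, ]), "two non-empty groups")
})

test_that("survival separates by planted gene-set hazard in the cohort", {
  cfg <- sim_config_scaled(seed = 31L, n_patients = 60L, target_mb = 2,
                           geneset_hr = 4)
  co <- simulate_cohort(cfg)
  truth <- co$geneset_truth
  d <- dplyr::inner_join(co$clinical, truth, by = "patient_id")
  d$mutated <- d$bcaa | d$hypoxia
  km <- km_logrank(d)
  expect_lt(km$p_value, 0.05)
  # mutated group dies faster
  curves <- tidy(km)
  med <- curves |>
    dplyr::group_by(group) |>
    dplyr::summarise(m = time[which(surv <= 0.5)[1]])
  expect_lt(med$m[med$group == "TRUE"], med$m[med$group == "FALSE"])
})

test_that("power formula agrees with Monte-Carlo rejection rates", {
  res <- power_sample_size(10, 2, 20, 11, 2, 20)
  mc <- mean(replicate(3000, {
    t.test(rnorm(20, 10, 2), rnorm(20, 11, 2))$p.value < 0.05
  }))
  expect_lt(abs(res$power - mc), 0.03)
  # zero effect: power = alpha, infinite required n
  null <- suppressWarnings(power_sample_size(10, 2, 20, 10, 2, 20))
  expect_equal(null$power, 0.05, tolerance = 1e-6)
  expect_equal(null$n_total_required, Inf)
  # huge effect: power ~ 1 and the requirement is tiny
  big <- power_sample_size(0, 1, 20, 3, 1, 20)
  expect_gt(big$power, 0.999)
  expect_lte(big$n_total_required, 10)
  # solving for 80% power self-checks against its own power formula
  d <- power_sample_size(14.23, 33.22, 41, 37.7, 19.32, 9)
  n1 <- ceiling(d$n_total_required / (1 + 9 / 41))
  n2 <- d$n_total_required - n1
  at_req <- power_sample_size(14.23, 33.22, n1, 37.7, 19.32, n2)
  expect_gte(at_req$power, 0.78)
})
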