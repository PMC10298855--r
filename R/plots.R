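#' Plot caller support
#'
#' Bar charts of call counts per caller and of merged variants by the
#' number of supporting callers.
#'
#' @param merged Output of [merge_callers()].
#' @return A patchable list of two ggplots is overkill here; a single
#'   faceted ggplot is returned.
#' @export
plot_support_histogram <- function(merged) {
  h <- support_histogram(merged)
  dat <- bind_rows(
    h$by_caller |> transmute(panel = "calls per caller",
                             x = caller, n = n),
    h$by_support |> transmute(panel = "callers in agreement",
                              x = as.character(n_callers), n = n)
  )
  ggplot(dat, aes(x = x, y = n)) +
    geom_col(fill = "steelblue") +
    facet_wrap(~panel, scales = "free_x") +
    labs(x = NULL, y = "variants") +
    theme_minimal()
}

#' Plot per-filter attrition
#'
#' How many variants each somatic filter removed (a variant may be
#' counted by several filters; all are evaluated).
#'
#' @param cascade A `cf_cascade` from [apply_cascade()].
#' @return A ggplot.
#' @export
plot_filter_attrition <- function(cascade) {
  dat <- cascade$trace |>
    group_by(filter_name) |>
    summarise(n_fired = sum(fired), .groups = "drop")
  ggplot(dat, aes(x = stats::reorder(filter_name, n_fired), y = n_fired)) +
    geom_col(fill = "firebrick") +
    coord_flip() +
    labs(x = NULL, y = "variants removed") +
    theme_minimal()
}

#' Plot burden by clinical group
#'
#' Jittered per-patient burden split by a clinical dichotomy.
#'
#' @param burden [compute_pmb()] output.
#' @param clinical Validated clinical tibble.
#' @param parameter Clinical dichotomy column name.
#' @param value Burden column (default `"pmb"`).
#' @return A ggplot.
#' @export
plot_burden <- function(burden, clinical, parameter = "metastasis",
                        value = "pmb") {
  dat <- inner_join(burden, clinical, by = "patient_id")
  dat$group <- as.factor(dat[[parameter]])
  dat$value <- dat[[value]]
  ggplot(dat, aes(x = group, y = value)) +
    geom_boxplot(outlier.shape = NA, width = 0.5) +
    geom_jitter(width = 0.12, alpha = 0.6, colour = "steelblue") +
    labs(x = parameter, y = "mutations / Mb") +
    theme_minimal()
}

#' Oncoprint-style mutation matrix plot
#'
#' Tile plot of the patient-by-gene nonsynonymous mutation matrix for the
#' most frequently mutated genes.
#'
#' @param matrix A [build_gene_matrix()] result.
#' @param n Number of top genes to show.
#' @return A ggplot.
#' @export
plot_gene_matrix <- function(matrix, n = 20L) {
  top <- top_mutated_genes(matrix, n)
  long <- as_tibble(matrix) |>
    tidyr::pivot_longer(-patient_id, names_to = "gene",
                        values_to = "mutated") |>
    filter(gene %in% top$gene) |>
    mutate(gene = factor(gene, levels = rev(top$gene)))
  ggplot(long, aes(x = patient_id, y = gene, fill = mutated)) +
    geom_tile(colour = "grey90") +
    scale_fill_manual(values = c(`FALSE` = "grey95", `TRUE` = "darkred")) +
    labs(x = "patient", y = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_blank(), legend.position = "none")
}

#' Kaplan-Meier plot
#'
#' Step curves of the two groups compared by [km_logrank()], annotated
#' with the log-rank p-value.
#'
#' @param object A `cf_km` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cf_km <- function(object, ...) {
  curves <- tidy(object) |>
    group_by(group) |>
    group_modify(~ bind_rows(tibble(time = 0, surv = 1,
                                    n_risk = max(.x$n_risk),
                                    n_event = 0L), .x)) |>
    ungroup()
  ggplot(curves, aes(x = time, y = surv, colour = group)) +
    geom_step(linewidth = 0.8) +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "time (days)", y = "overall survival",
         subtitle = sprintf("log-rank p = %.3g", object$p_value)) +
    theme_minimal()
}
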