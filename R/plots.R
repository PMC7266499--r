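#' Volcano plot of a differential table
#'
#' Log10 fold change against -log10 p, with the significance level and the
#' q-value cutoff highlighted.
#'
#' @param table A [differential_table()] output.
#' @param alpha Significance level drawn as a dashed line.
#' @param q_cutoff Proteins below this q-value are coloured.
#' @return A ggplot object.
#' @export
plot_volcano <- function(table, alpha = 0.05, q_cutoff = 0.05) {
  df <- dplyr::filter(table, !is.na(.data$p_value))
  df$status <- dplyr::case_when(
    df$q_value < q_cutoff ~ "q < cutoff",
    df$p_value < alpha ~ "p < alpha",
    TRUE ~ "n.s."
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$delta_log10,
                                   -log10(.data$p_value),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c("n.s." = "grey60",
                                            "p < alpha" = "steelblue",
                                            "q < cutoff" = "firebrick")) +
    ggplot2::labs(x = "log10 fold change (AD / non-AD)",
                  y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a data completeness curve
#'
#' @param curve Output of [completeness_curve()].
#' @return A ggplot object.
#' @export
plot_completeness_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(.data$min_samples, .data$n_proteins)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "minimum number of samples quantified in",
                  y = "number of proteins") +
    ggplot2::theme_minimal()
}

#' ROC curves of a k-fold evaluation
#'
#' One curve per fold plus the chance diagonal.
#'
#' @param object An `ml_report` from [kfold_evaluate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ml_report <- function(object, ...) {
  ggplot2::ggplot(object$roc,
                  ggplot2::aes(.data$fpr, .data$tpr,
                               group = .data$fold,
                               colour = factor(.data$fold))) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = "fold",
                  title = sprintf("mean AUC = %.3f", object$mean_auc)) +
    ggplot2::theme_minimal()
}

#' Enrichment score scatter for consistent annotation terms
#'
#' Mean enrichment score against term id for the cross-cohort consistent
#' terms; positive scores are AD-elevated.
#'
#' @param terms Output of [multi_cohort_terms()].
#' @return A ggplot object.
#' @export
plot_enrichment_terms <- function(terms) {
  df <- dplyr::arrange(terms, .data$mean_s)
  df$term_id <- factor(df$term_id, levels = df$term_id)
  ggplot2::ggplot(df, ggplot2::aes(.data$mean_s, .data$term_id,
                                   fill = .data$mean_s > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "mean enrichment score s", y = NULL) +
    ggplot2::theme_minimal()
}
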