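#' Plot sample scores along the activation axis
#'
#' Dot plot of PC1 sample scores by condition, in series order.
#'
#' @param object a `signature_model`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.signature_model <- function(object, ...) {
  df <- object$sample_scores
  df$condition <- factor(df$condition, levels = object$condition_order)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$score)) +
    ggplot2::geom_point(size = 2, colour = "#2c7fb8") +
    ggplot2::labs(
      x = NULL, y = "PC1 sample score",
      title = sprintf("Activation axis (%.1f%% of variance)",
                      100 * object$variance_explained)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the super-enhancer rank-score curve
#'
#' Normalized rank-score curve with the slope-1 tangent threshold; regions
#' above the threshold (the super-enhancers) are highlighted.
#'
#' @param object an `se_call`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.se_call <- function(object, ...) {
  cv <- object$curve
  if (!nrow(cv)) abort("no curve available (empty call)")
  cv$super <- cv$score > object$threshold_score
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$super)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = cv$x[max(which(!cv$super), 1)],
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "#d7301f"),
                                 guide = "none") +
    ggplot2::labs(
      x = "normalized rank", y = "normalized tag score",
      title = sprintf("%d super-enhancers (%s)", object$n_super,
                      object$condition)
    ) +
    ggplot2::theme_minimal()
}

#' Plot gene trends across the condition series
#'
#' One line per gene of 0-1 normalized expression across the ordered
#' conditions — the standard view of signature-gene trends.
#'
#' @param expr expression tibble.
#' @param sample_info sample annotation.
#' @param gene_group gene ids to draw.
#' @return a ggplot object.
#' @export
plot_gene_trends <- function(expr, sample_info, gene_group) {
  m <- expr_to_matrix(expr)
  cm <- condition_mean_matrix(m, sample_info)
  missing <- setdiff(gene_group, rownames(cm))
  if (length(missing)) abort("gene(s) not in matrix")
  cm <- cm[gene_group, , drop = FALSE]
  rng <- apply(cm, 1, function(v) diff(range(v)))
  norm <- (cm - apply(cm, 1, min)) / ifelse(rng == 0, 1, rng)
  df <- as_tibble(norm, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "condition",
                        values_to = "normalized")
  df$condition <- factor(df$condition, levels = colnames(cm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$normalized,
                                   group = .data$gene_id)) +
    ggplot2::geom_line(alpha = 0.25, colour = "#2c7fb8") +
    ggplot2::labs(x = NULL, y = "normalized RPKM (0-1)") +
    ggplot2::theme_minimal()
}

#' Plot a permutation-test null with the observed statistic
#'
#' @param object a `perm_trend_test`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.perm_trend_test <- function(object, ...) {
  df <- tibble(stat = object$null_values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed_statistic,
                        colour = "#d7301f", linewidth = 1) +
    ggplot2::labs(
      x = "permuted mean difference", y = "count",
      title = sprintf("z = %.2f, p = %.2g", object$z, object$p_two_tailed)
    ) +
    ggplot2::theme_minimal()
}
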