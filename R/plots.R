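#' Concordance plot of the two gene tests
#'
#' Scatter of -log10 p-values (set-screen vs simulation test) over the
#' shared gene universe, with the Bonferroni threshold drawn on both axes;
#' significant genes are highlighted.
#'
#' @param object A `gene_decisions` tibble from [decide()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gene_decisions <- function(object, ...) {
  d <- tidy(object)
  thr <- if (nrow(d)) -log10(d$threshold[1]) else NA_real_
  ggplot2::ggplot(d, ggplot2::aes(
    x = -log10(.data$p_a), y = -log10(.data$p_b),
    colour = .data$significant
  )) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = expression(-log[10] ~ p ~ "(set screen)"),
      y = expression(-log[10] ~ p ~ "(simulation test)"),
      colour = "significant"
    ) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression screen
#'
#' @param object A `de_results` tibble from [moderated_t()].
#' @param alpha Adjusted-p significance level to highlight, default 0.05.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.de_results <- function(object, alpha = 0.05, ...) {
  d <- tidy(object)
  d <- d[!is.na(d$p), , drop = FALSE]
  d$hit <- d$adj_p < alpha
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$log_fc, y = -log10(.data$p), colour = .data$hit
  )) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = expression(log[2] ~ "fold change (case - control)"),
      y = expression(-log[10] ~ p),
      colour = sprintf("adj p < %.2g", alpha)
    ) +
    ggplot2::theme_minimal()
}

#' Quantile-quantile plot of gene-level p-values
#'
#' @param results A scan tibble with a `gene_p` column.
#' @return A ggplot object comparing observed p-value quantiles with the
#'   uniform expectation.
#' @export
plot_gene_qq <- function(results) {
  p <- sort(results$gene_p)
  d <- tibble(
    expected = -log10(stats::ppoints(length(p))),
    observed = -log10(p)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10] ~ p),
      y = expression(Observed ~ -log[10] ~ p)
    ) +
    ggplot2::theme_minimal()
}
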