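#' Manhattan plot of an association scan
#'
#' Presentation helper (requires \pkg{ggplot2}); excluded from the
#' pipeline's determinism guarantees.
#'
#' @param assoc An `assoc_records` data frame.
#' @param threshold Optional horizontal significance line (p-value scale).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(assoc, threshold = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_manhattan requires ggplot2", call. = FALSE)
  }
  d <- as.data.frame(assoc)
  d$logp <- -log10(d$p_wald)
  p <- ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$pos / 1e6, y = .data$logp, colour = .data$chrom)
  ) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(
      yintercept = -log10(threshold),
      linetype = "dashed"
    )
  }
  p
}

#' Q-Q plot of observed versus expected p-values
#'
#' @param infl An [inflation_qq()] result.
#' @return A ggplot object annotated with the genomic inflation factor.
#' @export
plot_qq <- function(infl) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_qq requires ggplot2", call. = FALSE)
  }
  ggplot2::ggplot(
    infl$qq,
    ggplot2::aes(x = .data$expected, y = .data$observed)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::annotate("text",
      x = 0.5, y = max(infl$qq$observed),
      label = sprintf("lambda[gc] == %.3f", infl$lambda_gc), parse = TRUE,
      hjust = 0
    ) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p))
    ) +
    ggplot2::theme_minimal()
}
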