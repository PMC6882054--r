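#' Scatter true positive rate against false positive rate
#'
#' A thin ggplot2 layer over an outcomes table from [run_grid()] or
#' [aggregate_outcomes()]: one point per criterion and clinical threshold,
#' shaped by criterion and coloured by threshold, optionally facetted by
#' sample size. The ideal rule sits in the top-left corner.
#'
#' @param outcomes Data frame with `tpr`, `fpr`, `criterion`,
#'   `clinical_threshold` (and optionally `n_per_arm` for facetting).
#' @return A ggplot object.
#' @export
plot_tpr_fpr <- function(outcomes) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_tpr_fpr requires the ggplot2 package")
  p <- ggplot2::ggplot(
    outcomes,
    ggplot2::aes(x = fpr, y = tpr, shape = criterion,
                 colour = factor(clinical_threshold))
  ) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_shape_manual(
      values = rep(c(0:2, 5, 6, 15:18, 3, 4, 8),
                   length.out = length(unique(outcomes$criterion)))
    ) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = "Clinical threshold", shape = "Criterion") +
    ggplot2::theme_minimal()
  if ("n_per_arm" %in% names(outcomes))
    p <- p + ggplot2::facet_wrap(~n_per_arm, labeller = ggplot2::label_both)
  p
}

utils::globalVariables(c("fpr", "tpr", "criterion", "clinical_threshold"))
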