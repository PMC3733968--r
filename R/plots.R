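#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Null-distribution histogram for a pathway test
#'
#' Histogram of the permutation null proportions with the observed
#' proportion drawn as a vertical line — the standard way to display a
#' random-gene-set permutation test for one trait.
#'
#' @param object A `pathway_test` object.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pathway_test
#' @export
autoplot.pathway_test <- function(object, bins = 40, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_proportion)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = object$proportion_significant,
                        colour = "red", linewidth = 0.8) +
    ggplot2::labs(
      x = "proportion of significant SNPs in random gene sets",
      y = "replicates",
      title = sprintf("%s: f = %.3f, experiment-wise P = %.3f",
                      object$trait, object$proportion_significant,
                      object$experimentwise_p)) +
    ggplot2::theme_minimal()
}

#' @export
#' @rdname autoplot.pathway_test
#' @param x A `pathway_test` object.
plot.pathway_test <- function(x, ...) print(autoplot(x, ...))

#' Heat map of effect correlations
#'
#' @param object An `effect_corr` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot effect_corr
#' @export
autoplot.effect_corr <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trait_a, y = .data$trait_b,
                                   fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$correlation)), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "navy",
                                  mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("per-SNP effect correlations (%s)",
                                  object$selection_rule)) +
    ggplot2::theme_minimal()
}

#' P-value histogram for an association scan
#'
#' Quick calibration check: under the global null the per-SNP p-values
#' should be approximately uniform.
#'
#' @param assoc Association tibble from [assoc_scan()].
#' @param bins Number of bins.
#' @return A ggplot object, faceted by trait.
#' @export
plot_pvalue_histogram <- function(assoc, bins = 20) {
  ggplot2::ggplot(dplyr::filter(assoc, !is.na(.data$p_value)),
                  ggplot2::aes(x = .data$p_value)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, length.out = bins + 1),
                            fill = "grey40", colour = "white") +
    ggplot2::facet_wrap(ggplot2::vars(.data$trait)) +
    ggplot2::labs(x = "p-value", y = "SNPs") +
    ggplot2::theme_minimal()
}
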