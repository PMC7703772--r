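# Diagnostic plots. Each takes the tidy outputs of the evaluation module and
# returns a ggplot object, so everything composes with the usual grammar.

#' Mean-variance relationship per gene
#'
#' Log-log scatter of per-gene variance against mean with the Poisson
#' reference line (variance = mean); over-dispersed genes fan out above it.
#'
#' @param stats a [gene_stats()] tibble.
#' @return a ggplot.
#' @export
plot_mean_variance <- function(stats) {
  d <- dplyr::filter(stats, .data$mean > 0, .data$variance > 0)
  ggplot2::ggplot(d, ggplot2::aes(.data$mean, .data$variance)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mean expression", y = "variance",
                  title = "Mean-variance relationship")
}

#' Dropout rate versus mean expression
#'
#' Per-gene dropout fraction against mean observed expression, with the
#' parameter-free `exp(-mean)` reference curve (dotted). Under binomial
#' capture of NB-distributed counts the observed dropout hugs this curve for
#' weakly dispersed genes.
#'
#' @param stats a [gene_stats()] tibble.
#' @return a ggplot.
#' @export
plot_dropout_mean <- function(stats) {
  grid <- tibble::tibble(mean = exp(seq(log(max(min(stats$mean[stats$mean > 0]),
                                                1e-3)),
                                        log(max(stats$mean) + 1),
                                        length.out = 200)))
  grid$dropout <- dropout_approx_exp(grid$mean)
  ggplot2::ggplot(stats, ggplot2::aes(.data$mean, .data$dropout)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = grid, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mean expression", y = "dropout fraction",
                  title = "Dropout versus mean expression")
}

#' Distribution of per-cell dropout fractions
#'
#' @param dropout a [cell_dropout()] tibble.
#' @return a ggplot.
#' @export
plot_cell_dropout <- function(dropout) {
  ggplot2::ggplot(dropout, ggplot2::aes(.data$dropout)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::labs(x = "per-cell dropout fraction", y = "cells",
                  title = "Per-cell dropout distribution")
}

#' Log2-ratio recovery report as boxplots
#'
#' One box per statistic (mean, CV, Gini) of the per-gene log2 ratios of
#' recovered versus ground-truth values; perfect recovery sits at 0.
#'
#' @param report a [log_ratio_report()] tibble.
#' @return a ggplot.
#' @export
plot_log_ratios <- function(report) {
  d <- dplyr::filter(report, .data$finite)
  ggplot2::ggplot(d, ggplot2::aes(.data$statistic, .data$log2_ratio)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "log2(recovered / truth)",
                  title = "Recovery of distribution statistics")
}

#' @describeIn recover_counts mean-variance diagnostic of a recovery result
#'   (first sample slice for 3D output).
#' @param object a `recovered_counts` object.
#' @param ... unused.
#' @export
autoplot.recovered_counts <- function(object, ...) {
  v <- if (object$mode == "samples") object$values[, , 1L] else object$values
  plot_mean_variance(gene_stats(v)) +
    ggplot2::labs(title = sprintf("Mean-variance of recovered counts (%s)",
                                  object$mode))
}
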