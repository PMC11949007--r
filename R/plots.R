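#' Observed vs expected per-trio de novo count distribution
#'
#' Histogram of per-trio de novo counts with the fitted Poisson expectation
#' overlaid, the visual companion to [per_trio_gof()].
#'
#' @param counts integer vector of per-trio de novo counts.
#' @return a ggplot object.
#' @export
plot_denovo_distribution <- function(counts) {
  kmax <- max(counts, 1)
  df <- tibble::tibble(k = 0:kmax,
                       observed = tabulate(counts + 1L, nbins = kmax + 1L),
                       expected = length(counts) * dpois(0:kmax, mean(counts)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed), fill = "grey70") +
    ggplot2::geom_point(ggplot2::aes(y = .data$expected), colour = "firebrick") +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected), colour = "firebrick") +
    ggplot2::labs(x = "de novo variants per trio", y = "trios",
                  title = "Per-trio de novo counts vs Poisson expectation") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.poisson_gof <- function(object, ...) {
  df <- object$bins
  df$bin <- factor(df$bin, levels = df$bin)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed), fill = "grey70") +
    ggplot2::geom_point(ggplot2::aes(y = .data$expected), colour = "firebrick") +
    ggplot2::labs(x = "count bin (pooled)", y = "trios",
                  subtitle = sprintf("X2 = %.2f, df = %s, p = %s",
                                     object$statistic, format(object$df),
                                     format.pval(object$p_value))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.burden_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$consequence_class)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$expected), fill = "grey80") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 3,
                        colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "de novo count",
                  title = "Observed (points) vs expected (bars) de novo burden") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.digenic_screen <- function(object, ...) {
  df <- object$stage_counts
  df$stage <- factor(df$stage, levels = rev(df$stage))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$stage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), hjust = -0.2, size = 3) +
    ggplot2::labs(x = "count", y = NULL, title = "Digenic screen pipeline flow") +
    ggplot2::theme_minimal()
}
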