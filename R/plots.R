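# ggplot2 autoplot() methods for the package's result objects.

#' Plot a duration trend
#'
#' Bin medians with IQR ribbon over years with disease, annotated with
#' the Pearson correlation of bin medians against bin midpoints.
#'
#' @param object A [duration_trend()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
#' @method autoplot duration_trend
autoplot.duration_trend <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$midpoint, y = .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Years with disease (bin midpoint)",
      y = sprintf("Median %s", attr(object, "measure")),
      subtitle = sprintf("Pearson r = %.2f%s", attr(object, "r"),
                         if (is.na(attr(object, "p.value"))) "" else
                           sprintf(" (p = %.3g)", attr(object, "p.value")))
    )
}

#' Plot a block-wise decomposition
#'
#' Per-block increments of Nagelkerke r2, stacked in model order.
#'
#' @param object A [hierarchical_decomposition()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
#' @method autoplot decomposition_result
autoplot.decomposition_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$block <- factor(df$block, levels = df$block)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$block, y = .data$delta_r2)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("cum. %.3f", .data$r2)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "Block (added successively)",
                  y = expression(Delta ~ "Nagelkerke" ~ r^2),
                  subtitle = sprintf("total r2 = %.3f (n = %d)",
                                     df$r2[nrow(df)], attr(object, "n")))
}

#' Plot the adjustment map
#'
#' The composed quantile-mapping curve against the identity over a raw
#' measurement range.
#'
#' @param object An [adjustment_model()].
#' @param from,to Raw value range to draw.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
#' @method autoplot adjustment_model
autoplot.adjustment_model <- function(object, from = 15, to = 60, ...) {
  x <- seq(from, to, length.out = 200)
  df <- tibble::tibble(raw = x, adjusted = adjust_value(object, x))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$raw, y = .data$adjusted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = sprintf("Raw %s", object$measure),
                  y = sprintf("Adjusted %s", object$measure))
}

#' Plot a resampling distribution
#'
#' Histogram of per-replicate Nagelkerke r2 with the median marked.
#'
#' @param object A [matched_female_resampling()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
#' @method autoplot resampling_result
autoplot.resampling_result <- function(object, ...) {
  ggplot2::ggplot(object$replicates, ggplot2::aes(x = .data$r2)) +
    ggplot2::geom_histogram(bins = 20) +
    ggplot2::geom_vline(xintercept = object$median_r2, linetype = 2) +
    ggplot2::labs(x = expression("Nagelkerke" ~ r^2 ~ "per matched group"),
                  y = "Replicates",
                  subtitle = sprintf("median r2 = %.3f over %d groups of %d",
                                     object$median_r2, object$n_groups,
                                     object$group_size))
}
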