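#' Plot a voltage trace with its stimulus
#'
#' @param object A `voltage_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.voltage_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_ms, .data$voltage_mv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "membrane potential (mV)") +
    ggplot2::theme_minimal()
}

#' Plot a step-count table and its fitted linear model
#'
#' @param object A `step_model_fit`.
#' @param ... Unused.
#' @return A ggplot object showing total steps vs AP count with the fitted
#'   baseline + per-spike line.
#' @export
autoplot.step_model_fit <- function(object, ...) {
  df <- object$lm$model
  ggplot2::ggplot(df, ggplot2::aes(.data$ap_count, .data$steps)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$steps_base,
                         slope = object$steps_ap, color = "steelblue") +
    ggplot2::labs(x = "action potentials", y = "integration steps / s",
                  subtitle = sprintf("steps_base = %.0f, steps_ap = %.0f",
                                     object$steps_base, object$steps_ap)) +
    ggplot2::theme_minimal()
}

#' Plot nested cluster assignments in level-1 PCA space
#'
#' @param object A `cluster_tree`.
#' @param ... Unused.
#' @return A ggplot of the first two level-1 components colored by final
#'   leaf label.
#' @export
autoplot.cluster_tree <- function(object, ...) {
  sc <- object$level1$scores
  df <- tibble(PC1 = sc[, 1],
               PC2 = if (ncol(sc) >= 2) sc[, 2] else 0,
               label = object$assignments$final_label)
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                   color = .data$label)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(color = "cluster") +
    ggplot2::theme_minimal()
}

#' Bar plot of NCD summaries with bootstrap intervals
#'
#' @param summary Tibble from [summarize_ncd()].
#' @return A ggplot of mean NCD per channel cluster, faceted by cell
#'   cluster, with the bootstrap confidence intervals as error bars.
#' @export
plot_ncd_summary <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(.data$channel_cluster, .data$mean_ncd)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.25) +
    ggplot2::facet_wrap(~cell_cluster) +
    ggplot2::labs(x = "channel cluster", y = "normalized channel density") +
    ggplot2::theme_minimal()
}
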