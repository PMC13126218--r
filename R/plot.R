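#' Plot a calibration curve
#'
#' Draws the estimated average-cluster curve with its confidence band
#' (dark) and prediction band (light), the diagonal of perfect
#' calibration, and optionally the cluster-specific curves.
#'
#' @param object A `calibration_curve`.
#' @param show_clusters Overlay cluster-specific curves where available.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.calibration_curve <- function(object, show_clusters = FALSE, ...) {
  df <- tibble::as_tibble(object)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$grid, y = .data$estimate))
  if (any(is.finite(df$pi_lo))) {
    gg <- gg + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$pi_lo, ymax = .data$pi_hi),
      fill = "steelblue", alpha = 0.15, na.rm = TRUE)
  }
  if (any(is.finite(df$ci_lo))) {
    gg <- gg + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
      fill = "steelblue", alpha = 0.35, na.rm = TRUE)
  }
  pc <- attr(object, "per_cluster")
  if (show_clusters && !is.null(pc)) {
    gg <- gg + ggplot2::geom_line(
      data = pc,
      ggplot2::aes(x = .data$grid, y = .data$estimate,
                   group = .data$cluster),
      colour = "grey60", linewidth = 0.3, alpha = 0.7)
  }
  gg +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_line(colour = "steelblue4", linewidth = 0.8) +
    ggplot2::geom_point(size = if (nrow(df) <= 15) 1.6 else 0) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Predicted risk", y = "Observed proportion",
                  title = paste0("Calibration curve (",
                                 attr(object, "method_tag"), ")")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.calibration_curve
#' @param x A `calibration_curve`.
#' @param y Unused.
#' @export
plot.calibration_curve <- function(x, y, ...) {
  print(autoplot.calibration_curve(x, ...))
}
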