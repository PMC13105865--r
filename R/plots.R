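#' Reliability diagram for a calibration report
#'
#' Per-bin accuracy against mean confidence with the diagonal of perfect
#' calibration; point size tracks bin occupancy.
#'
#' @param object A `calibration_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calibration_report <- function(object, ...) {
  df <- dplyr::filter(object$bins, .data$occupancy > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$confidence, y = .data$accuracy)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = .data$occupancy)) +
    ggplot2::geom_line() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "mean confidence (bin)", y = "accuracy (bin)",
      size = "samples",
      title = sprintf("Reliability diagram (ECE = %.3f)", object$ece)
    ) +
    ggplot2::theme_minimal()
}

#' Coverage-risk curve plot
#'
#' @param curve Tibble from [coverage_risk_curve()].
#' @param points Optional tibble of operating points from
#'   [selective_operating_points()].
#' @return A ggplot object.
#' @export
plot_coverage_risk <- function(curve, points = NULL) {
  p <- ggplot2::ggplot(dplyr::filter(curve, !is.na(.data$risk)),
                       ggplot2::aes(x = .data$coverage, y = .data$risk)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "coverage (accepted fraction)",
                  y = "risk (error among accepted)") +
    ggplot2::theme_minimal()
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(data = points, colour = "red", size = 2)
  }
  p
}

#' Fold-level accuracy distribution of a cross-validation run
#'
#' @param object A `xonet_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.xonet_cv <- function(object, ...) {
  ggplot2::ggplot(object$fold_metrics,
                  ggplot2::aes(x = factor(.data$repeat_id), y = .data$accuracy)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
    ggplot2::labs(x = "repeat", y = "test-fold accuracy") +
    ggplot2::theme_minimal()
}

#' Top attribution scores per subtype
#'
#' @param attributions Aggregated tibble from [aggregate_attributions()].
#' @param top_n Markers shown per subtype.
#' @return A ggplot object.
#' @export
plot_attributions <- function(attributions, top_n = 10L) {
  df <- attributions |>
    dplyr::group_by(.data$subtype) |>
    dplyr::slice_max(.data$score, n = top_n, with_ties = FALSE) |>
    dplyr::ungroup()
  label_col <- if ("node" %in% names(df)) "node" else "edge_id"
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$score,
    y = stats::reorder(as.character(.data[[label_col]]), .data$score)
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~subtype, scales = "free_y") +
    ggplot2::labs(x = "mean |attribution|", y = NULL) +
    ggplot2::theme_minimal()
}
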