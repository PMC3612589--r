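#' Plot a rendered flow field
#'
#' Draws the flow as arrows on the image plane, coloured by layer. Note the
#' frame convention: x grows to the left, so the horizontal axis is reversed
#' to display the scene as seen by the observer.
#'
#' @param object A `flow_field` from [render_flow_field()].
#' @param arrow_scale Multiplier from m/s to displayed metres; defaults to
#'   a scale that makes the longest arrow one cell long.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flow_field <- function(object, arrow_scale = NULL, ...) {
  speed <- sqrt(object$u^2 + object$v^2)
  if (is.null(arrow_scale)) {
    arrow_scale <- attr(object, "dx") / max(speed, na.rm = TRUE)
  }
  df <- dplyr::mutate(
    as_tibble(object),
    xend = .data$x + .data$u * arrow_scale,
    yend = .data$y + .data$v * arrow_scale
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$xend, yend = .data$yend,
                   colour = .data$layer),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.8, "mm")),
      linewidth = 0.3
    ) +
    ggplot2::scale_x_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (m, leftward)", y = "y (m)", colour = "layer") +
    ggplot2::theme_minimal()
}

#' Plot heading-bias curves of a heading experiment
#'
#' Mean error (with one standard deviation across conditions) against the
#' object's path angle, split by FOE visibility group.
#'
#' @param report An `experiment_report` from [run_heading_experiment()]
#'   (Warren & Saunders layout).
#' @return A ggplot object.
#' @export
plot_heading_bias <- function(report) {
  sm <- summarise_experiment(report)
  ggplot2::ggplot(sm, ggplot2::aes(.data$path_angle_deg,
                                   .data$mean_bias_deg)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_bias_deg - .data$sd_bias_deg,
                   ymax = .data$mean_bias_deg + .data$sd_bias_deg),
      width = 0.5
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$group)) +
    ggplot2::labs(x = "path angle (deg)", y = "heading error (deg)") +
    ggplot2::theme_minimal()
}

#' Plot radius-ratio curves of the path experiment
#'
#' @param report An `experiment_report` from [run_path_experiment()].
#' @return A ggplot object.
#' @export
plot_radius_ratio <- function(report) {
  ggplot2::ggplot(report, ggplot2::aes(.data$radius, .data$ratio,
                                       colour = .data$path)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "path radius (m)", y = "estimated / true radius") +
    ggplot2::theme_minimal()
}
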