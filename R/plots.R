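# ggplot2 methods for each result type. All plots draw the CSR reference
# level (value 1) where it is meaningful.

#' Plot an occupancy grid
#'
#' @param object an [occupancy_grid()].
#' @param ... unused.
#' @return a ggplot: occupied sites with the domain circle(s) overlaid.
#' @export
autoplot.occupancy_grid <- function(object, ...) {
  pos <- position_set(object)
  circ <- tibble(
    angle = seq(0, 2 * pi, length.out = 361)
  )
  p <- ggplot2::ggplot(pos, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 0.1, alpha = 0.6) +
    ggplot2::geom_path(data = transform(circ, x = object$R * cos(angle),
                                        y = object$R * sin(angle)),
                       linetype = "dashed", colour = "grey40") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (lattice units)", y = "y (lattice units)") +
    ggplot2::theme_minimal()
  if (object$R_A > 0) {
    p <- p + ggplot2::geom_path(
      data = transform(circ, x = object$R_A * cos(angle),
                       y = object$R_A * sin(angle)),
      linetype = "dotted", colour = "grey40")
  }
  p
}

#' Plot a metric signal
#'
#' Draws the CSR-normalised signal against its bin left edges with the
#' CSR reference at 1; axis labels follow the signal kind.
#'
#' @param object a [colony_signal].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.colony_signal <- function(object, ...) {
  kind <- attr(object, "kind")
  lab <- switch(kind,
    radial = c("radial distance r", expression(F[r])),
    angular = c(expression(theta), expression(F[theta])),
    pair_angle = c(expression(Theta), expression(F[Theta]))
  )
  ggplot2::ggplot(object, ggplot2::aes(x = .data$left_edge, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = lab[[1]], y = lab[[2]]) +
    ggplot2::theme_minimal()
}

#' Plot an angular spectrum
#'
#' Spectral power `|f_k|^2` at positive wavenumbers.
#'
#' @param object an [angular_spectrum()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.angular_spectrum <- function(object, ...) {
  d <- object[object$k >= 1, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$power)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$k, yend = 0)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "wavenumber k", y = expression(abs(hat(f)[k])^2)) +
    ggplot2::theme_minimal()
}

#' Plot sample-averaged index trajectories
#'
#' Mean of each index over the colony sample against time, with error
#' bars of one standard error of the mean and the fitted trend curve when
#' available.
#'
#' @param object a `colony_sample_summary` from [summarize_sample()].
#' @param indices which indices to show (default the four scalar indices).
#' @param ... unused.
#' @return a ggplot faceted by index.
#' @export
autoplot.colony_sample_summary <- function(object,
                                           indices = c("I_r", "I_theta",
                                                       "I_Theta", "I_a"),
                                           ...) {
  d <- tidy(object)
  d <- d[d$index %in% indices, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "index") +
    ggplot2::theme_minimal()
  if (!is.null(object$fits)) {
    curves <- trend_curves(object)
    curves <- curves[curves$index %in% indices, ]
    p <- p + ggplot2::geom_line(data = curves,
                                ggplot2::aes(x = .data$t, y = .data$fitted),
                                colour = "grey40")
  }
  p
}
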