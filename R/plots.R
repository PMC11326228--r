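#' Plot a wall-motion field
#'
#' Envelope (plus/minus) and a displacement snapshot at `t_s`.
#'
#' @param object A `wall_motion_field`.
#' @param t_s Snapshot time, s.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wall_motion_field <- function(object, t_s = 0, ...) {
  x <- seq(0, object$x_max_mm, length.out = 600)
  prof <- wave_profile(object, x)
  snap <- wall_motion(object, x, t_s)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$x_mm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = -.data$A_um, ymax = .data$A_um),
                         fill = "grey85") +
    ggplot2::geom_line(data = snap,
                       ggplot2::aes(y = .data$displacement_um),
                       colour = "steelblue") +
    ggplot2::labs(x = "distance from base (mm)",
                  y = "wall displacement (µm)",
                  title = sprintf("%g-Hz %s wave", object$f_hz,
                                  if (object$standing) "standing" else "traveling")) +
    ggplot2::theme_minimal()
}

#' Plot the drift (steady-streaming) field
#'
#' Axial drift velocity as a heat map over the two-layer section, with the
#' membrane marked. Positive values stream toward the apex.
#'
#' @param object A `flow_solution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flow_solution <- function(object, ...) {
  td <- tidy(object)
  g <- object$grid
  p <- ggplot2::ggplot(td, ggplot2::aes(.data$x_mm, .data$y_um,
                                        fill = .data$u_um_s)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = "distance from base (mm)", y = "height (µm)",
                  fill = "axial drift\n(µm/s)") +
    ggplot2::theme_minimal()
  if (!is.na(g$j_mem)) {
    p <- p + ggplot2::geom_hline(yintercept = g$ny_s * g$dy * 1e6,
                                 linetype = 2, linewidth = 0.3)
  }
  p
}

#' Plot concentration profiles of a delivery run
#'
#' Observation-line concentration against distance at a handful of times
#' (log-spaced), on a logarithmic concentration scale.
#'
#' @param object A `delivery_run`.
#' @param times_min Times to display (defaults to 5 log-spaced times).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.delivery_run <- function(object, times_min = NULL, ...) {
  td <- tidy(object)
  tmax <- max(td$time_s)
  if (is.null(times_min)) {
    times_min <- exp(seq(log(tmax / 100), log(tmax), length.out = 5)) / 60
  }
  pick <- vapply(times_min * 60, function(t0) {
    object$times_s[which.min(abs(object$times_s - t0))]
  }, numeric(1))
  dd <- dplyr::filter(td, .data$time_s %in% pick, .data$conc_mM > 1e-6)
  dd$time_min <- factor(round(dd$time_s / 60, 2))
  ggplot2::ggplot(dd, ggplot2::aes(.data$x_mm, .data$conc_mM,
                                   colour = .data$time_min)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::geom_hline(yintercept = object$config$f_thr * object$config$C0,
                        linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "distance from base (mm)", y = "concentration (mM)",
                  colour = "time (min)") +
    ggplot2::theme_minimal()
}

#' Plot an effect-time dataset against its diffusion trend
#'
#' @param object A `diffusion_trend`.
#' @param ... Unused.
#' @return A ggplot object (log-log axes).
#' @export
autoplot.diffusion_trend <- function(object, ...) {
  xr <- range(object$data$x_mm)
  line <- tibble(x_mm = seq(xr[1], xr[2], length.out = 100))
  line$t_e_min <- predict(object, line$x_mm)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$x_mm, .data$t_e_min)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = line, linetype = 2, colour = "firebrick") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "place (mm from base)", y = "effect time (min)") +
    ggplot2::theme_minimal()
}

#' Plot normalised driven-response curves
#'
#' @param curve Output of [driven_response_curve()].
#' @param criterion Criterion line to draw (default 0.75).
#' @return A ggplot object.
#' @export
plot_response_curves <- function(curve, criterion = 0.75) {
  stopifnot(is.data.frame(curve))
  d <- dplyr::mutate(curve, channel = factor(.data$channel))
  ggplot2::ggplot(d, ggplot2::aes(.data$t_min, .data$normalized,
                                  colour = .data$channel)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = criterion, linetype = 2, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, linewidth = 0.3) +
    ggplot2::labs(x = "time after application (min)",
                  y = "normalised driven response") +
    ggplot2::theme_minimal()
}
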