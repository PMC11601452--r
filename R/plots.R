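# ggplot2 graphics for the package's result types.

#' @export
autoplot.population_rate <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$rate_hz)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "population rate (Hz)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.spatial_heatmap <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, !is.na(.data$value)),
                  ggplot2::aes(x = .data$x_um, y = .data$y_um,
                               fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cwt_spectrogram <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$time_s, y = .data$freq_hz,
                               fill = log10(.data$power + 1e-12))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(name = "log10 power") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.angle_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_centre, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue", width = 2 * pi / nrow(object)) +
    ggplot2::coord_polar(start = pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(-pi, pi),
                                breaks = c(-pi / 2, 0, pi / 2, pi),
                                labels = c("-90°", "0°", "90°",
                                           "180°")) +
    ggplot2::labs(x = NULL, y = "weighted count") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.circuit_pairs <- function(object, arrow_um = 40, ...) {
  df <- as_tibble(object)
  df$xend <- df$x_source + arrow_um * cos(df$angle)
  df$yend <- df$y_source + arrow_um * sin(df$angle)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x_source, y = .data$y_source,
                   xend = .data$xend, yend = .data$yend,
                   colour = .data$angle),
      arrow = ggplot2::arrow(length = ggplot2::unit(1.6, "mm"))) +
    ggplot2::scale_colour_gradientn(
      colours = c("#d73027", "#1a9850", "#d73027"),
      limits = c(-pi, pi), name = "angle (rad)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.phase_heatmap <- function(object, ...) {
  autoplot.spatial_heatmap(object$heatmap) +
    ggplot2::labs(fill = "|Δ phase| (rad)")
}

#' @export
autoplot.connectivity_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fraction,
                                       y = .data$synchrony_index)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "line", colour = "firebrick") +
    ggplot2::labs(x = "GC interconnect fraction", y = "synchrony index") +
    ggplot2::theme_minimal()
}

#' Plot one theta-wave spatial frame
#'
#' Red marks positive theta voltage, blue negative; circle size scales with
#' magnitude, mirroring the wave-activity video convention.
#'
#' @param frames A [theta_frames()] object.
#' @param time_s Frame time (nearest frame is used).
#' @return A ggplot.
#' @export
plot_theta_frame <- function(frames, time_s) {
  stopifnot(inherits(frames, "theta_frames"))
  i <- which.min(abs(frames$times_s - time_s))
  df <- frames$electrodes
  df$value <- frames$values[, i]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                   size = abs(.data$value),
                                   colour = .data$value > 0)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c("TRUE" = "#d73027",
                                            "FALSE" = "#4575b4"),
                                 guide = "none") +
    ggplot2::scale_size_area(max_size = 3, limits = c(0, 1), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("theta frame @ %.3f s", frames$times_s[i]),
                  x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}
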