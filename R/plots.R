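#' Plot a reconstructed WET frame
#'
#' Raster of the WET map in mm water; masked (uncovered) pixels are blank.
#'
#' @param object A `frame_image`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.frame_image <- function(object, ...) {
  df <- tidyr::expand_grid(x = grid_x_mm(object$grid),
                           y = grid_y_mm(object$grid))
  # expand_grid varies the last column fastest; wet is stored x-major
  df <- df[order(df$y, df$x), ]
  df$wet <- as.vector(object$wet)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$wet)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", name = "WET (mm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("frame %s, t = %.2f s",
                                  object$frame_index, object$frame_timestamp)) +
    ggplot2::theme_minimal()
}

#' Plot measured vs expected insert position over time
#'
#' @param object A `tracking_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tracking_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_frame,
                            c("measured_mm", "expected_mm"),
                            names_to = "series", values_to = "offset_mm")
  df$series <- ifelse(df$series == "measured_mm", "measured", "expected")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timestamp, y = .data$offset_mm,
                                   colour = .data$series,
                                   linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = df[df$series == "measured", ]) +
    ggplot2::labs(x = "time (s)", y = "offset from field centre (mm)",
                  colour = NULL, linetype = NULL,
                  subtitle = sprintf("MAE = %.2f +/- %.2f mm",
                                     object$mae, object$sigma)) +
    ggplot2::theme_minimal()
}

#' Plot a scan pattern's visit order
#'
#' @param pattern A [make_scan_pattern()] tibble.
#' @param frame Frame to show (default 1).
#' @return A ggplot.
#' @export
plot_scan_pattern <- function(pattern, frame = 1) {
  df <- pattern[pattern$frame_index == frame, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_mm, y = .data$y_mm)) +
    ggplot2::geom_path(colour = "red") +
    ggplot2::geom_point(shape = 4) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("%s scan, frame %d",
                                  attr(pattern, "pattern_type"), frame)) +
    ggplot2::theme_minimal()
}
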