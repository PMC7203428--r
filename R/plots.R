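#' Plot player localizations on the court
#'
#' Court-plane view of one frame's result: optimized localizations as filled
#' points, fallback localizations as open diamonds, with the court outline.
#'
#' @param object a `player_localizations` from [localize_frame()].
#' @param court_x,court_y court extent in metres.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.player_localizations <- function(object, court_x = 14, court_y = 15,
                                          ...) {
  loc <- object$localizations
  loc <- loc[loc$method != "unlocalized", , drop = FALSE]
  court <- data.frame(x = c(0, court_x, court_x, 0, 0),
                      y = c(0, 0, court_y, court_y, 0))
  ggplot2::ggplot(loc, ggplot2::aes(x = .data$X, y = .data$Y)) +
    ggplot2::geom_path(data = court, ggplot2::aes(x = .data$x, y = .data$y),
                       inherit.aes = FALSE, colour = "grey55") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$method,
                                     colour = factor(.data$label)),
                        size = 3) +
    ggplot2::scale_shape_manual(values = c(optimized = 16, fallback = 5)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "X (m)", y = "Y (m)", colour = "player",
                  shape = "method", title = "3D player localizations (court plane)") +
    ggplot2::theme_minimal()
}

#' Plot detections over a frame
#'
#' @param detections tibble with `x`, `y` (and optionally `radius_px`).
#' @param frame optional grayscale matrix drawn underneath.
#' @param truth optional tibble of ground-truth head points (`x`, `y`).
#' @return a ggplot object.
#' @export
plot_detections <- function(detections, frame = NULL, truth = NULL) {
  p <- ggplot2::ggplot()
  if (!is.null(frame)) {
    df <- data.frame(x = as.vector(row(frame)), y = as.vector(col(frame)),
                     v = as.vector(frame))
    p <- p + ggplot2::geom_raster(data = df,
                                  ggplot2::aes(x = .data$x, y = .data$y,
                                               fill = .data$v)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white",
                                   guide = "none")
  }
  if (!is.null(truth) && nrow(truth)) {
    p <- p + ggplot2::geom_point(data = truth,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 shape = 3, colour = "green3", size = 3)
  }
  if (nrow(detections)) {
    p <- p + ggplot2::geom_point(data = detections,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 shape = 1, colour = "red", size = 3)
  }
  p + ggplot2::scale_y_reverse() + ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)") + ggplot2::theme_minimal()
}
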