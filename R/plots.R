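#' @describeIn area_histogram Histogram bars with the relative-frequency curve
#'   overlaid on a secondary axis.
#' @param object An `adipo_histogram`.
#' @param ... Unused.
#' @export
autoplot.adipo_histogram <- function(object, ...) {
  df <- as_tibble(object)
  df$bin_mid <- (df$bin_start + df$bin_end) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey30") +
    ggplot2::geom_line(ggplot2::aes(y = .data$relative_frequency *
                                      max(df$count) / max(df$relative_frequency, 1)),
                       colour = "firebrick") +
    ggplot2::labs(
      x = "Cell area (µm²)", y = "Cells per bin",
      title = sprintf("Adipocyte size distribution (n = %d)", attr(object, "n_cells"))
    ) +
    ggplot2::theme_minimal()
}

#' @rdname bland_altman
#' @param object A `bland_altman` object.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(
      x = "Mean of methods (µm²)",
      y = sprintf("Difference (%s, µm²)", object$orientation),
      title = sprintf("Bland-Altman: bias %.3g, 95%% LoA [%.3g, %.3g]",
                      object$bias, object$loa_low, object$loa_high)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname regression_r2
#' @param object A `method_regression` object.
#' @export
autoplot.method_regression <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "Method x (µm²)", y = "Method y (µm²)",
      title = sprintf("y = %.3g x + %.3g,  R² = %.4f",
                      object$slope, object$intercept, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Overlay detections on an image
#'
#' QC view: the grayscale image with detection centroids marked, scaled so a
#' reviewer can confirm that segmented particles are adipocyte lumina.
#'
#' @param img A [calibrated_image()].
#' @param detections Detection tibble for that image.
#' @param max_px Downsample target: the longer image side is reduced to at
#'   most this many pixels before plotting (default 800).
#'
#' @return A ggplot object.
#' @export
plot_detections <- function(img, detections, max_px = 800) {
  assert_image(img)
  f <- max(1L, ceiling(max(dim(img$pixels)) / max_px))
  small <- if (f > 1L) downsample(img, f) else img
  px <- small$pixels
  df <- tibble(
    x = rep(seq_len(ncol(px)), each = nrow(px)),
    y = rep(seq_len(nrow(px)), times = ncol(px)),
    value = as.vector(px)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::geom_point(
      data = tibble(x = detections$centroid_x_px / f, y = detections$centroid_y_px / f),
      colour = "red", shape = 3, size = 1
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%d detections", nrow(detections))) +
    ggplot2::theme_void()
}
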