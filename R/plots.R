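#' Plot a map over the grid
#'
#' Raster view of any map (saliency, activation, inhibition, priority,
#' probability) in degree coordinates.
#'
#' @param M Numeric matrix over grid cells.
#' @param grid An [sw_grid()].
#' @param name Fill legend title.
#' @return A ggplot object.
#' @export
plot_map <- function(M, grid, name = "value") {
  stopifnot(is_sw_grid(grid))
  df <- tibble(
    x = rep(grid$xs, times = grid$n_y),
    y = rep(grid$ys, each = grid$n_x),
    value = as.vector(M)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = name) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "x (deg)", y = "y (deg)")
}

#' Plot scan paths over an optional saliency map
#'
#' @param fixations Fixation tibble.
#' @param saliency Optional saliency matrix (single image).
#' @param grid An [sw_grid()] (required with `saliency`).
#' @return A ggplot object.
#' @export
plot_scanpath <- function(fixations, saliency = NULL, grid = NULL) {
  p <- if (!is.null(saliency)) {
    plot_map(saliency, grid, name = "saliency")
  } else {
    ggplot2::ggplot() + ggplot2::coord_fixed() +
      ggplot2::labs(x = "x (deg)", y = "y (deg)")
  }
  key <- interaction(fixations$subject, fixations$image,
                     if ("path" %in% names(fixations)) fixations$path else 1)
  df <- tibble(x = fixations$x_deg, y = fixations$y_deg, path = key)
  p +
    ggplot2::geom_path(data = df,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$path),
                       color = "white", linewidth = 0.3) +
    ggplot2::geom_point(data = df,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        color = "orange", size = 1)
}

#' Plot a turning-angle or direction histogram with subject bands
#'
#' @param summary_tbl One element of [distribution_summaries()].
#' @param xlab Axis label.
#' @return A ggplot object.
#' @export
plot_angle_histogram <- function(summary_tbl, xlab = "angle (deg)") {
  ggplot2::ggplot(summary_tbl, ggplot2::aes(x = .data$bin,
                                            y = .data$mean_density)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$band_lower,
                                      ymax = .data$band_upper),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::labs(x = xlab, y = "density")
}

#' Plot the saccade-relative landing density
#'
#' @param rel Result of [relative_saccade_density()].
#' @return A ggplot object; the previous saccade ran from (-1, 0) to the
#'   origin.
#' @export
plot_relative_density <- function(rel) {
  ggplot2::ggplot(rel$density, ggplot2::aes(x = .data$x, y = .data$y,
                                            fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "density") +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::annotate("point", x = c(-1, 0), y = c(0, 0),
                      color = "white", shape = 3) +
    ggplot2::labs(x = "x (previous amplitude)", y = "y (previous amplitude)")
}

#' Trace plot of posterior draws
#'
#' @param object An `sw_fit` object.
#' @param ... Unused.
#' @return A ggplot object with one facet per parameter, chains colored.
#' @export
autoplot.sw_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$draws,
                              dplyr::all_of(object$priors$param),
                              names_to = "param", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iter, y = .data$value,
                                     color = factor(.data$chain))) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~param, scales = "free_y") +
    ggplot2::labs(color = "chain", x = "iteration", y = NULL)
}
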