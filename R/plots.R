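#' Plotting helpers
#'
#' ggplot2 views of the package's result types: traced contour stacks,
#' method-comparison tables, and phantom sections with segmentation
#' overlays.
#'
#' @name plots
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a contour table, faceted by section
#'
#' @param object A contour table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.glom_contours <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               group = .data$contour_id,
                               fill = .data$compartment)) +
    ggplot2::geom_polygon(alpha = 0.6, colour = "grey20", linewidth = 0.2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~section_index, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_manual(values = c(mesangium = "#c0392b",
                                          tuft = "#f1c9b8",
                                          other = "grey70")) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = "Traced compartment contours") +
    ggplot2::theme_minimal()
}

#' Per-method distribution of a measurement table
#'
#' Mirrors the usual method-comparison figure: one point per unit per method
#' with the method means drawn as crossbars.
#'
#' @param table A complete-case table from [measurement_table()].
#' @return A ggplot.
#' @export
plot_method_comparison <- function(table) {
  means <- table |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(table, ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$unit), colour = "grey75") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$method), size = 2) +
    ggplot2::geom_crossbar(data = means,
                           ggplot2::aes(ymin = .data$value,
                                        ymax = .data$value),
                           width = 0.4, linewidth = 0.4) +
    ggplot2::labs(x = NULL, y = "Mesangial volume (µm³)",
                  title = "Method comparison (lines join the same unit)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' QC overlay of segmentation contours on a section image
#'
#' @param img RGB array `[rows, cols, 3]`, 0..255.
#' @param contours Contours for this section (um coordinates with the image
#'   origin at 0,0).
#' @param pixel_size_um Pixel size in um.
#' @return A ggplot.
#' @export
plot_section_overlay <- function(img, contours, pixel_size_um) {
  h <- nrow(img) * pixel_size_um
  w <- ncol(img) * pixel_size_um
  raster <- grDevices::as.raster(pmin(pmax(img / 255, 0), 1))
  closed <- contours |>
    dplyr::group_by(.data$contour_id, .data$compartment) |>
    dplyr::group_modify(~dplyr::bind_rows(.x, .x[1, ])) |>
    dplyr::ungroup()
  ggplot2::ggplot() +
    ggplot2::annotation_raster(raster, xmin = 0, xmax = w,
                               ymin = -h, ymax = 0) +
    ggplot2::geom_path(data = closed,
                       ggplot2::aes(x = .data$x, y = -.data$y,
                                    group = .data$contour_id,
                                    colour = .data$compartment),
                       linewidth = 0.4) +
    ggplot2::scale_colour_manual(values = c(mesangium = "#2040c0",
                                            tuft = "#108040",
                                            other = "grey40")) +
    ggplot2::coord_fixed(xlim = c(0, w), ylim = c(-h, 0), expand = FALSE) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}
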