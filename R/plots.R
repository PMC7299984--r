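#' Plot a raster stack
#'
#' Pixel map of each layer, faceted by time label. Missing pixels are blank.
#'
#' @param object A [raster_stack].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.raster_stack <- function(object, ...) {
  df <- as_tibble.raster_stack(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~time) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = paste0(object$variable_name,
                                ifelse(nzchar(object$units),
                                       paste0(" [", object$units, "]"), "")),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a simulated scene's ground truth
#'
#' Map of the true cooling-constant field the simulator embedded.
#'
#' @param object A [make_scene()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sim_scene <- function(object, ...) {
  autoplot.raster_stack(
    raster_stack(object$truth_k, object$grid, "truth_k",
                 variable_name = "true k", units = "1/hr")
  ) + ggplot2::labs(title = "Simulated true cooling constant")
}

#' Plot an RMA fit
#'
#' Scatter of the two measurements with the fitted reduced-major-axis line
#' and the 1:1 line.
#'
#' @param object An [rma_regression()] fit.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rma_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         color = "red") +
    ggplot2::labs(x = object$x_name, y = object$y_name,
                  subtitle = sprintf("RMA slope %.3f, intercept %.3g, r = %.3f",
                                     object$slope, object$intercept,
                                     object$pearson_r)) +
    ggplot2::theme_minimal()
}

#' Plot a correlation table
#'
#' Tile map with Pearson coefficients above the diagonal and Spearman below,
#' the conventional layout for cross-correlation summaries.
#'
#' @param object A [correlation_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.correlation_table <- function(object, ...) {
  vn <- object$variable_names
  df <- tidy.correlation_table(object) |>
    dplyr::mutate(
      i = match(.data$var1, vn), j = match(.data$var2, vn),
      r = dplyr::case_when(.data$j > .data$i ~ .data$pearson,
                           .data$j < .data$i ~ .data$spearman,
                           TRUE ~ 1)
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$j, .data$i, fill = abs(.data$r))) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradientn(colors = c("#d7191c", "#ffffbf", "#1a9641"),
                                  limits = c(0, 1), name = "|r|") +
    ggplot2::scale_x_continuous(breaks = seq_along(vn), labels = vn,
                                position = "top") +
    ggplot2::scale_y_reverse(breaks = seq_along(vn), labels = vn) +
    ggplot2::labs(x = NULL, y = NULL,
                  subtitle = "Pearson above diagonal, Spearman below") +
    ggplot2::theme_minimal()
}

#' Plot a trend classification raster
#'
#' Maps the five Mann-Kendall significance classes with the conventional
#' diverging palette (greens for decreasing decay rate — increasing
#' vegetation — reds for increasing).
#'
#' @param trend A [trend_map()] result (or a class-code [raster_stack]).
#' @return A ggplot.
#' @export
plot_trend_map <- function(trend) {
  classes <- if (inherits(trend, "raster_stack")) trend else trend$classes
  df <- as_tibble.raster_stack(classes) |>
    dplyr::mutate(class = factor(trend_class_levels[.data$value],
                                 levels = trend_class_levels))
  pal <- c(decreasing_p05 = "#1a9641", decreasing_p10 = "#a6d96a",
           none = "#f7f7f7", increasing_p10 = "#fdae61",
           increasing_p05 = "#d7191c")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = pal, na.value = "grey80",
                               drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "trend",
                  caption = "increasing decay rate = decreasing vegetation") +
    ggplot2::theme_minimal()
}
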