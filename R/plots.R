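#' Scatter plot of two features coloured by cell type
#'
#' The headless counterpart of the interactive feature scatter: relevant
#' cells only, coloured by assigned type (unclassified cells in grey).
#'
#' @param table A classified feature table.
#' @param x,y Namespaced feature names.
#' @param types Optional list of [cell_type()] definitions supplying colours.
#' @return A ggplot object.
#' @export
plot_feature_scatter <- function(table, x, y, types = list()) {
  check_feature_cols(table, c(x, y), "plot_feature_scatter")
  rel <- table[table$relevant, ]
  colmap <- c(stats::setNames(
    vapply(types, `[[`, character(1), "color"),
    vapply(types, `[[`, character(1), "name")),
    unknown = "#808080")
  ggplot2::ggplot(rel, ggplot2::aes(x = .data[[x]], y = .data[[y]],
                                    colour = .data$cell_type)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = colmap, na.value = "#808080") +
    ggplot2::labs(x = x, y = y, colour = "cell type") +
    ggplot2::theme_minimal()
}

#' @rdname plot_feature_scatter
#' @param object A `ct_result` from [run_single()] (uses the configured
#'   scatter features).
#' @param ... Unused.
#' @export
autoplot.ct_result <- function(object, ...) {
  s <- object$config$report$scatter
  if (is.null(s)) stop("no scatter features configured; use plot_feature_scatter()")
  plot_feature_scatter(object$table, s$x, s$y, object$config$cell_types)
}

#' Plot quadrant counts
#'
#' @param object A `ct_quadrants` from [quadrant_counts()].
#' @param ... Unused.
#' @return A ggplot object (2x2 tile plot of the counts).
#' @export
autoplot.ct_quadrants <- function(object, ...) {
  df <- tibble::tibble(
    x = c("low", "low", "high", "high"),
    y = c("low", "high", "low", "high"),
    n = c(object$n_LL, object$n_LH, object$n_HL, object$n_HH))
  df$x <- factor(df$x, c("low", "high"))
  df$y <- factor(df$y, c("low", "high"))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::labs(x = attr(object, "feature_x"), y = attr(object, "feature_y")) +
    ggplot2::theme_minimal()
}

#' Plot a fitted curve over its data
#'
#' @param object A `ct_fit` from [fit_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ct_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#d62728") +
    ggplot2::labs(title = sprintf("%s fit, R^2 = %.4f", object$model,
                                  object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic scene's Marker I plane with truth centres
#'
#' @param object A `ct_scene` from [generate_scene()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ct_scene <- function(object, ...) {
  m <- object$markers$MarkerI
  df <- tibble::tibble(
    x = rep(0:(ncol(m) - 1), each = nrow(m)),
    y = rep(0:(nrow(m) - 1), ncol(m)),
    value = as.vector(m))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (nrow(object$truth) > 0)
    p <- p + ggplot2::geom_point(
      data = object$truth, ggplot2::aes(.data$cx, .data$cy),
      inherit.aes = FALSE, colour = "#d62728", shape = 3)
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
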