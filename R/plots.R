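# ggplot2 visualisations for result objects

#' @rdname plots
#' @param object A result object.
#' @param ... Unused.
#' @name plots
NULL

#' @rdname plots
#' @exportS3Method ggplot2::autoplot
autoplot.parallel_analysis <- function(object, ...) {
  df <- tidyr::pivot_longer(object$eigenvalues, c("observed", "simulated"),
                            names_to = "series", values_to = "eigenvalue")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = .data$eigenvalue,
                                   linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$suggested_n_factors + 0.5,
                        colour = "grey50", linetype = 3) +
    ggplot2::labs(x = "Component", y = "Eigenvalue",
                  title = sprintf("Parallel analysis: %d factors suggested",
                                  object$suggested_n_factors)) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @exportS3Method ggplot2::autoplot
autoplot.factor_solution <- function(object, ...) {
  df <- tidy(object)
  df$item <- factor(df$item, levels = rev(rownames(object$pattern)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = .data$item,
                                   fill = .data$pattern)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "loading",
                  title = sprintf("Pattern loadings (%s)", object$rotation)) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @exportS3Method ggplot2::autoplot
autoplot.pcor_network <- function(object, ...) {
  p <- length(object$nodes)
  ang <- seq(0, 2 * pi, length.out = p + 1)[-(p + 1)]
  layout <- tibble(node = object$nodes, x = cos(ang), y = sin(ang))
  edges <- network_edges(object)
  edges <- dplyr::left_join(edges, layout, by = c("node_a" = "node"))
  edges <- dplyr::left_join(edges, layout, by = c("node_b" = "node"),
                            suffix = c("", "_end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_end,
                   yend = .data$y_end, linewidth = abs(.data$weight),
                   colour = .data$weight > 0, alpha = abs(.data$weight))) +
    ggplot2::geom_point(data = layout, ggplot2::aes(.data$x, .data$y),
                        size = 9, colour = "grey85") +
    ggplot2::geom_text(data = layout,
                       ggplot2::aes(.data$x, .data$y, label = .data$node),
                       size = 2.6) +
    ggplot2::scale_linewidth(range = c(0.2, 2), guide = "none") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "steelblue",
                                            `FALSE` = "firebrick"),
                                 guide = "none") +
    ggplot2::scale_alpha(range = c(0.3, 1), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' @rdname plots
#' @exportS3Method ggplot2::autoplot
autoplot.regression_profile <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::facet_wrap(~outcome) +
    ggplot2::labs(x = "standardized beta", y = NULL) +
    ggplot2::theme_minimal()
}
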