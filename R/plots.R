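# ggplot2 visualisations for the workbench's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

surface_grid <- function(space, n = 101) {
  tidyr::expand_grid(
    !!space$factor[1] := seq(space$low[1], space$high[1], length.out = n),
    !!space$factor[2] := seq(space$low[2], space$high[2], length.out = n)
  )
}

#' Response-surface contour plot of a fitted model
#'
#' Filled contours of the predicted response over the two-factor region with
#' the design points overlaid.
#'
#' @param object An `rsm_fit`.
#' @param n Grid resolution per axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rsm_fit <- function(object, n = 101, ...) {
  space <- object$space
  abort_if(nrow(space) != 2, "surface plots need exactly two factors")
  g <- surface_grid(space, n)
  g$response <- predict(object, g)
  f1 <- space$factor[1]; f2 <- space$factor[2]
  ggplot2::ggplot(g, ggplot2::aes(.data[[f1]], .data[[f2]], z = .data$response)) +
    ggplot2::geom_contour_filled(bins = 12) +
    ggplot2::geom_point(data = as.data.frame(object$design),
                        ggplot2::aes(.data[[f1]], .data[[f2]]),
                        inherit.aes = FALSE, colour = "red", size = 2) +
    ggplot2::labs(title = paste("Response surface:", object$response),
                  fill = object$response) +
    ggplot2::theme_minimal()
}

#' Plot a release profile
#'
#' Corrected cumulative release (mg) against time with the sampled raw
#' concentrations as a secondary layer of points.
#'
#' @param object A `release_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.release_profile <- function(object, ...) {
  cr <- suppressWarnings(cumulative_release(object))
  ggplot2::ggplot(cr, ggplot2::aes(.data$time_h, .data$cumulative_mg)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (h)", y = "cumulative release (mg)",
                  title = "In-vitro release") +
    ggplot2::theme_minimal()
}

#' Plot a rheological temperature sweep
#'
#' Storage modulus on a log axis against temperature; when a sol-gel
#' transition is detectable its interval is shaded.
#'
#' @param object A `rheo_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rheo_sweep <- function(object, ...) {
  d <- tibble::tibble(temperature = object$temperatures, g_prime = object$g_prime)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$temperature, .data$g_prime)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "temperature (degC)", y = "G' (Pa)",
                  title = "Storage modulus sweep") +
    ggplot2::theme_minimal()
  det <- tryCatch(detect_sol_gel(object), error = function(e) NULL)
  if (!is.null(det)) {
    p <- p + ggplot2::annotate("rect", xmin = det$interval[1],
                               xmax = det$interval[2], ymin = -Inf, ymax = Inf,
                               alpha = 0.2, fill = "steelblue") +
      ggplot2::geom_vline(xintercept = det$t_solgel, linetype = 2)
  }
  p
}

#' Plot the composite-desirability surface of an optimization
#'
#' Filled contours of the coarse-grid composite desirability with the
#' optimum marked.
#'
#' @param object An `optimum_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.optimum_result <- function(object, ...) {
  space <- object$space
  abort_if(nrow(space) != 2, "desirability surface plots need two factors")
  f1 <- space$factor[1]; f2 <- space$factor[2]
  opt <- tibble::as_tibble(as.list(object$factors))
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(.data[[f1]], .data[[f2]], z = .data$D)) +
    ggplot2::geom_contour_filled(bins = 12) +
    ggplot2::geom_point(data = opt, ggplot2::aes(.data[[f1]], .data[[f2]]),
                        inherit.aes = FALSE, colour = "red", shape = 8,
                        size = 3) +
    ggplot2::labs(title = sprintf("Composite desirability (D = %.3f at optimum)",
                                  object$D), fill = "D") +
    ggplot2::theme_minimal()
}
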