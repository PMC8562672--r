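# ggplot2 methods for the package's result types.

#' @method autoplot saxs_profile
#' @export
autoplot.saxs_profile <- function(object, log_y = TRUE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$q, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = expression(q ~ (nm^-1)), y = "intensity (a.u.)",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @method autoplot saxs_peaks
#' @export
autoplot.saxs_peaks <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$order, y = .data$amplitude)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$order, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Bragg order n", y = "|F_n| (a.u.)",
                  subtitle = sprintf("d_M = %.2f nm", attr(object, "d_M"))) +
    ggplot2::theme_minimal()
}

#' @method autoplot axial_profile
#' @export
autoplot.axial_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x_frac, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "fractional D-period coordinate",
                  y = "density (a.u.)", subtitle = attr(object, "role")) +
    ggplot2::theme_minimal()
}

#' @method autoplot phasing_result
#' @export
autoplot.phasing_result <- function(object, ...) {
  autoplot(object$rho_gl) +
    ggplot2::labs(
      title = "Retrieved glycation density",
      subtitle = sprintf("resolution %.2f nm, %d cycles",
                         object$resolution_nm, nrow(object$cycle_log)))
}

#' @method autoplot slope_fit
#' @export
autoplot.slope_fit <- function(object, ...) {
  df <- object$fit$model
  names(df) <- c("y", "t")[seq_len(ncol(df))]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::labs(x = "incubation time (days)",
                  y = "squared relative variation") +
    ggplot2::theme_minimal()
}

#' @method autoplot glycation_prediction
#' @export
autoplot.glycation_prediction <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$t_years, y = 100 * .data$fraction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (years)", y = "glycated sites (%)",
                  subtitle = sprintf("%s, %g mg/ml", attr(object, "sugar"),
                                     attr(object, "concentration"))) +
    ggplot2::theme_minimal()
}

#' Plot a 2D residue or proximity map
#'
#' @param map Matrix (rows = lateral y, columns = periodic axial x).
#' @param title Plot title.
#' @return A ggplot.
#' @export
plot_map <- function(map, title = "proximity map") {
  df <- tidyr::expand_grid(y = seq_len(nrow(map)), x = seq_len(ncol(map)))
  df$value <- as.vector(t(map))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "axial pixel", y = "lateral pixel", title = title) +
    ggplot2::theme_minimal()
}
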