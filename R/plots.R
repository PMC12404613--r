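#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot binned residual medians for each neutrality function
#'
#' Reproduces the standard residual-versus-severity figure: per-law median
#' residual (with interquartile ribbon) against the maximum single-mutant
#' fitness bin midpoints.
#'
#' @param object A `neutrality_fit` from [fit_neutrality()] or a
#'   `binned_residuals` table from [bin_residuals()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.neutrality_fit <- function(object, ...) {
  autoplot.binned_residuals(object$bins, ...)
}

#' @rdname autoplot.neutrality_fit
#' @export
autoplot.binned_residuals <- function(object, ...) {
  dat <- dplyr::filter(object, .data$n > 0)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin_mid, y = .data$median,
                                    colour = .data$law, fill = .data$law)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "maximum single-mutant fitness",
                  y = "residual (observed - predicted)",
                  colour = "neutrality function",
                  fill = "neutrality function") +
    ggplot2::theme_minimal()
}

#' Heatmap of mean absolute deviations per parameter pair and law
#'
#' @param object A `weisse_scan_matrix` from [weisse_scan_all()].
#' @param ... Unused.
#' @return A ggplot object: parameter pairs (rows) by neutrality function
#'   (columns), filled by log10 mean absolute deviation.
#' @export
autoplot.weisse_scan_matrix <- function(object, ...) {
  dat <- dplyr::mutate(object,
                       pair = paste(.data$param_a, .data$param_b, sep = " : "))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$law, y = .data$pair,
                                    fill = log10(.data$mean_abs_deviation))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10 mean |deviation|") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Line plot of the gamma sweep
#'
#' @param object A `weisse_gamma_sweep` table.
#' @param ... Unused.
#' @return A ggplot object of median absolute Product residual against
#'   gamma (both axes log scale).
#' @export
autoplot.weisse_gamma_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$gamma,
                               y = .data$median_abs_residual_product)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(gamma),
                  y = "median | Product residual |") +
    ggplot2::theme_minimal()
}
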