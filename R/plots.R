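#' Plot an isolation-by-distance fit
#'
#' Scatter of pairwise linearized F_ST against geographic distance with
#' the fitted OLS line.
#'
#' @param object An `ibd_fit` from [ibd_regression()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ibd_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$distance_km, y = .data$linearized_fst)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         linewidth = 0.4) +
    ggplot2::labs(x = "Geographic distance (km)",
                  y = expression(F[ST] / (1 - F[ST])),
                  subtitle = sprintf("slope = %.3g per km, R² = %.2f",
                                     object$slope, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot the dispersal-spread uncertainty
#'
#' Histogram of the Monte-Carlo sigma draws with the point estimate and
#' the 95% percentile interval marked.
#'
#' @param object A `sigma_estimate` from [propagate_sigma()].
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sigma_estimate <- function(object, bins = 80, ...) {
  df <- tibble::tibble(sigma = object$draws)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sigma)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = NA) +
    ggplot2::geom_vline(xintercept = object$sigma_point, linewidth = 0.6) +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        linetype = "dashed") +
    ggplot2::coord_cartesian(
      xlim = c(0, unname(quantile(object$draws, 0.999)))) +
    ggplot2::labs(x = expression(sigma ~ "(km)"), y = "draws",
                  subtitle = sprintf("point %.1f km, 95%% interval [%.1f, %.1f] km",
                                     object$sigma_point, object$ci_low,
                                     object$ci_high)) +
    ggplot2::theme_minimal()
}

#' Plot a focal-site connectivity regression
#'
#' @param object A `focal_fit` from [connectivity_vs_genetics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.focal_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$connectivity, y = .data$linearized_fst)) +
    ggplot2::geom_point(shape = 1) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         linetype = "dotted") +
    ggplot2::labs(x = "Potential connectivity",
                  y = expression(F[ST] / (1 - F[ST])),
                  subtitle = sprintf("site %s: R² = %.2f, p = %.3g",
                                     object$focal_site, object$r_squared,
                                     object$p_value)) +
    ggplot2::theme_minimal()
}
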