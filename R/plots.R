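#' Plots
#'
#' ggplot2 figures for the distribution fits, recovery curves and mesh
#' matches.
#'
#' @name plots
NULL

#' Histogram of samples with the fitted density
#'
#' @param fit an `aqua_fit` from [fit_normal()] or [fit_lognormal()].
#' @param bins histogram bins.
#' @return a ggplot object.
#' @export
plot_distance_fit <- function(fit, bins = 60) {
  df <- tibble::tibble(x = fit$samples)
  dens <- if (fit$family == "normal")
    function(x) stats::dnorm(x, fit$mu, fit$sigma)
  else
    function(x) stats::dlnorm(x, fit$mu, fit$sigma)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey40") +
    ggplot2::geom_function(fun = dens, colour = "red", linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = if (fit$family == "normal") fit$mu
                        else fit$median, linetype = "dashed") +
    ggplot2::labs(x = if (fit$family == "normal") "distance (Å)"
                  else "deviation (Å)", y = "density") +
    ggplot2::theme_minimal()
}

#' @rdname plot_distance_fit
#' @param object an `aqua_fit`.
#' @param ... passed on.
#' @method autoplot aqua_fit
#' @export
autoplot.aqua_fit <- function(object, ...) plot_distance_fit(object, ...)

#' Recovery-rate curve over distance cut-offs
#'
#' @param deviations per-sphere central-water deviations (`NA` = no
#'   prediction), or a precomputed [recovery_rate()] tibble.
#' @param cutoffs cut-off grid, Angstrom.
#' @return a ggplot object.
#' @export
plot_recovery_curve <- function(deviations, cutoffs = seq(0.1, 2.5, by = 0.1)) {
  df <- if (is.data.frame(deviations)) deviations
        else recovery_rate(deviations, cutoffs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutoff, y = .data$recovery_percent)) +
    ggplot2::geom_line(colour = "steelblue", linewidth = 0.9) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "distance cut-off (Å)", y = "recovery rate (%)") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Matched and unmatched waters of a mesh comparison
#'
#' @param object an `aqua_match`.
#' @param ... unused.
#' @return a ggplot object (deviation histogram of matched pairs).
#' @method autoplot aqua_match
#' @export
autoplot.aqua_match <- function(object, ...) {
  df <- object$pairs
  ggplot2::ggplot(df, ggplot2::aes(x = .data$deviation)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = "dashed") +
    ggplot2::labs(x = "pair deviation (Å)", y = "matches") +
    ggplot2::theme_minimal()
}
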