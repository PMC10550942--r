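#' Broom-style tidiers
#'
#' `tidy()` returns per-component tables (fit parameters, matched water
#' pairs), `glance()` one-row model summaries.
#'
#' @name tidiers
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidiers
#' @param x an `aqua_fit` or `aqua_match` object.
#' @param ... unused.
#' @method tidy aqua_fit
#' @export
tidy.aqua_fit <- function(x, ...) {
  tibble::tibble(
    term = if (x$family == "normal") c("mu", "sigma") else c("meanlog", "sdlog"),
    estimate = c(x$mu, x$sigma))
}

#' @rdname tidiers
#' @method glance aqua_fit
#' @export
glance.aqua_fit <- function(x, ...) {
  out <- tibble::tibble(family = x$family, mu = x$mu, sigma = x$sigma, n = x$n)
  if (x$family == "lognormal") {
    out$median <- x$median
    out$mode <- x$mode
  }
  out
}

#' @rdname tidiers
#' @method tidy aqua_match
#' @export
tidy.aqua_match <- function(x, ...) x$pairs

#' @rdname tidiers
#' @method glance aqua_match
#' @export
glance.aqua_match <- function(x, ...) {
  tibble::tibble(
    tp_percent = x$tp_percent, fp_percent = x$fp_percent,
    fn_percent = x$fn_percent, mean_deviation = x$mean_deviation,
    n_predicted = x$n_predicted, n_reference = x$n_reference,
    cutoff = x$cutoff, method = x$method)
}
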