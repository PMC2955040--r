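# ggplot2 graphics: fitted curves over the data, velocity/acceleration
# profiles, and multi-model / multi-arm overlays.

curve_tbl <- function(fit, n = 300, window = NULL) {
  window <- window %||% range(fit$series$time)
  tt <- seq(window[1], window[2], length.out = n)
  tibble::tibble(time = tt, weight = predict(fit, tt), family = fit$family)
}

#' Plot a fitted growth curve over the observations
#'
#' @param object A `growth_fit`.
#' @param n Number of curve evaluation points.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.growth_fit <- function(object, n = 300, ...) {
  ggplot2::ggplot(object$series, ggplot2::aes(.data$time, .data$weight)) +
    ggplot2::geom_line(data = curve_tbl(object, n), color = "#2166ac") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (days)", y = "tumor weight (g)",
      title = sprintf("%s fit (SSE = %.3g)", object$family, object$sse)) +
    ggplot2::theme_minimal()
}

#' Plot velocity and acceleration profiles
#'
#' @param object A `growth_dynamics` object.
#' @param ... Unused.
#' @return A ggplot (faceted: rate and acceleration), with the rate maximum
#'   marked.
#' @export
autoplot.growth_dynamics <- function(object, ...) {
  long <- tidyr::pivot_longer(object$profile, c("rate", "acceleration"),
    names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::geom_vline(xintercept = object$t_max, linetype = "dashed") +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = NULL,
      title = sprintf("%s dynamics: max rate %.4g g/day on day %.2f",
        object$family, object$v_max, object$t_max)) +
    ggplot2::theme_minimal()
}

#' Overlay fitted curves or rate profiles from several fits
#'
#' `plot_growth_curves()` overlays the fitted weight curves (with the data
#' of the first fit's series when all fits share it); `plot_rate_curves()`
#' overlays the analytic growth-rate profiles.
#'
#' @param fits List of `growth_fit` objects.
#' @param labels Curve labels; default family names (or arm labels if set).
#' @param window Time window (days); default the union of observed ranges.
#' @param n Evaluation points per curve.
#' @return A ggplot.
#' @export
plot_growth_curves <- function(fits, labels = NULL, window = NULL, n = 300) {
  labels <- labels %||% vapply(fits, function(f) f$family, character(1))
  window <- window %||% range(unlist(lapply(fits, function(f) f$series$time)))
  curves <- purrr::map2_dfr(fits, labels, function(f, lab) {
    dplyr::mutate(curve_tbl(f, n, window), curve = lab)
  })
  pts <- dplyr::bind_rows(purrr::map2(fits, labels, function(f, lab) {
    dplyr::mutate(tibble::as_tibble(f$series), curve = lab)
  }))
  ggplot2::ggplot(curves, ggplot2::aes(.data$time, .data$weight,
      color = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = pts, alpha = 0.6) +
    ggplot2::labs(x = "time (days)", y = "tumor weight (g)", color = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_growth_curves
#' @export
plot_rate_curves <- function(fits, labels = NULL, window = NULL, n = 300) {
  labels <- labels %||% vapply(fits, function(f) f$family, character(1))
  window <- window %||% range(unlist(lapply(fits, function(f) f$series$time)))
  rates <- purrr::map2_dfr(fits, labels, function(f, lab) {
    tt <- seq(max(window[1], 1e-6), window[2], length.out = n)
    tibble::tibble(time = tt, rate = growth_rate(f$params, tt), curve = lab)
  })
  ggplot2::ggplot(rates, ggplot2::aes(.data$time, .data$rate,
      color = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)", y = "growth rate (g/day)", color = NULL) +
    ggplot2::theme_minimal()
}
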