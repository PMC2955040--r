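# Model-comparison statistics: AIC under a Gaussian error model, residual
# mean square, R-squared, and mean absolute relative error, plus AIC-based
# ranking across families fitted to the same series.

#' Mean absolute relative error
#'
#' `mean(|observed - predicted| / observed)`. The denominator is the
#' observed value, so all observations must be strictly positive.
#'
#' @param observed,predicted Numeric vectors of equal length (grams).
#' @return A unitless non-negative scalar.
#' @examples
#' mare(c(1, 2), c(1.1, 1.8)) # 0.1
#' @export
mare <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    rlang::abort("observed and predicted must have equal length.",
      class = "hyperbolastic_input_error")
  }
  if (any(observed == 0)) {
    rlang::abort("MARE divides by the observed values; zeros are not allowed.",
      class = "hyperbolastic_input_error")
  }
  mean(abs(observed - predicted) / observed)
}

#' Residual mean square
#'
#' `SSE / (n - k)`: the unbiased residual-variance estimate of a
#' k-parameter least-squares fit, in grams^2.
#'
#' @param sse Residual sum of squares (grams^2).
#' @param n Number of observations.
#' @param k Number of fitted mean-function parameters.
#' @return Residual mean square (grams^2).
#' @export
rms_error <- function(sse, n, k) {
  if (n <= k) {
    rlang::abort("residual mean square needs n > k.",
      class = "hyperbolastic_input_error")
  }
  sse / (n - k)
}

#' Gaussian AIC from a residual sum of squares
#'
#' `n * log(2 * pi * SSE / n) + n + 2 * k`, the Akaike information
#' criterion of a least-squares fit under i.i.d. Gaussian errors with the
#' variance profiled out, counting only the `k` mean-function parameters.
#' (This equals `stats::AIC()` on the equivalent Gaussian model minus the
#' `+2` that `stats::AIC()` adds for the variance parameter.) Lower is
#' better. A perfect fit (`sse = 0`) returns `-Inf`, which ranks first.
#'
#' @inheritParams rms_error
#' @return AIC (unitless).
#' @export
aic_gaussian <- function(sse, n, k) {
  if (n <= 0 || sse < 0) {
    rlang::abort("need n > 0 and sse >= 0.", class = "hyperbolastic_input_error")
  }
  if (sse == 0) return(-Inf)
  n * log(2 * pi * sse / n) + n + 2 * k
}

#' Coefficient of determination
#'
#' `1 - SSE / SST` with `SST = sum((obs - mean(obs))^2)`.
#'
#' @inheritParams mare
#' @return R-squared (unitless, at most 1).
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2) {
    rlang::abort("need equal-length vectors with n >= 2.",
      class = "hyperbolastic_input_error")
  }
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) {
    rlang::abort("R-squared is undefined for a constant observed vector.",
      class = "hyperbolastic_input_error")
  }
  1 - sum((observed - predicted)^2) / sst
}

# AIC ordering, ties broken by smaller k.
rank_metrics <- function(tbl) {
  tbl <- dplyr::arrange(tbl, .data$aic, .data$k)
  dplyr::mutate(tbl, rank = dplyr::row_number())
}

#' Rank fitted models on one series
#'
#' Builds the model-comparison report: per family the AIC, residual mean
#' square, R-squared and MARE, ordered by AIC (lowest first, ties broken by
#' the smaller parameter count). All fits must be to the same series.
#'
#' @param fits A list of `growth_fit` objects on the same data.
#' @return A tibble of class `model_comparison` with one row per family,
#'   ranked; the best family is in `attr(, "best_model")`.
#' @examples
#' series <- ehrlich_tumor()
#' fits <- lapply(c("H3", "gompertz"), function(f) fit_growth(series, f))
#' rank_models(fits)
#' @export
rank_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2,
    all(vapply(fits, inherits, logical(1), "growth_fit")))
  ref <- fits[[1]]$series
  same <- vapply(fits, function(f) {
    isTRUE(all.equal(f$series$time, ref$time)) &&
      isTRUE(all.equal(f$series$weight, ref$weight))
  }, logical(1))
  if (!all(same)) {
    rlang::abort("all fits must be to the same series.",
      class = "hyperbolastic_input_error")
  }
  tbl <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(family = f$family, k = f$k, sse = f$sse,
      aic = aic_gaussian(f$sse, f$n, f$k),
      rms = rms_error(f$sse, f$n, f$k),
      r_squared = r_squared(f$series$weight, f$fitted),
      mare = mare(f$series$weight, f$fitted))
  })
  tbl <- rank_metrics(tbl)
  attr(tbl, "best_model") <- tbl$family[1]
  class(tbl) <- c("model_comparison", class(tbl))
  tbl
}

#' Fit several families and rank them
#'
#' Convenience wrapper: [fit_growth()] for each requested family on one
#' series, then [rank_models()].
#'
#' @inheritParams fit_growth
#' @param families Character vector of family names (default: all five).
#' @param ... Passed to [fit_growth()].
#' @return A `model_comparison` tibble; the fits are kept in
#'   `attr(, "fits")` (named by family).
#' @export
compare_models <- function(data, families = FAMILIES, ...) {
  series <- as_growth_series(data)
  families <- vapply(families, canon_family, character(1))
  fits <- lapply(families, function(f) fit_growth(series, f, ...))
  names(fits) <- families
  out <- rank_models(fits)
  attr(out, "fits") <- fits
  out
}
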