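# Nonlinear least-squares fitting
#
# Estimation minimizes sum (w_i - P(t_i))^2 with minpack.lm's bounded
# Levenberg-Marquardt, re-anchoring alpha at (t0, P0) on every objective
# evaluation. Two families carry near-degenerate scale parameters (H3's
# delta ~ 1e-9 against gamma ~ 5, Weibull's beta likewise), so those are
# optimized on a log10 scale internally and reported on the natural scale.

# Evaluate a family's curve from natural-scale free parameters.
eval_curve <- function(family, nat, t0, P0, t) {
  p <- do.call(growth_params,
    c(list(family = family), as.list(nat), list(t0 = t0, P0 = P0)))
  predict(p, t)
}

internal_scaled <- function(family) {
  switch(family, H3 = "delta", weibull = "beta", NULL)
}

to_internal <- function(family, nat) {
  s <- internal_scaled(family)
  if (!is.null(s)) nat[s] <- log10(max(nat[s], 1e-15))
  nat
}

from_internal <- function(family, int) {
  s <- internal_scaled(family)
  if (!is.null(s)) int[s] <- 10^int[s]
  int
}

fit_bounds <- function(family, max_w) {
  Mb <- c(max_w * (1 + 1e-6), 10 * max_w)
  switch(family,
    H1 = list(lower = c(M = Mb[1], delta = 0, theta = -10),
              upper = c(M = Mb[2], delta = 10, theta = 10)),
    H2 = list(lower = c(M = Mb[1], delta = 0, gamma = 1e-3),
              upper = c(M = Mb[2], delta = 10, gamma = 10)),
    H3 = list(lower = c(M = Mb[1], delta = -15, gamma = 1e-3, theta = 0),
              upper = c(M = Mb[2], delta = 1, gamma = 10, theta = 10)),
    gompertz = list(lower = c(b = -50, c = -5),
                    upper = c(b = -1e-8, c = -1e-8)),
    weibull = list(lower = c(M = Mb[1], beta = -15, gamma = 1e-3),
                   upper = c(M = Mb[2], beta = 1, gamma = 10)))
}

#' Heuristic starting values for a fit
#'
#' Builds a starting parameter vector from simple linearizations:
#' `M0 = 1.05 * max(weight)`; Gompertz `b0, c0` from regressing
#' `log(log(M0/w))` on `t`; the time-power `gamma0` (H2, H3, Weibull) from
#' the slope of `log(-log((M0 - w)/M0))` against `log(t)`; the associated
#' rate scale (`delta0` or `beta0`) from a log-linear regression at that
#' `gamma0`; `theta0` small and positive.
#'
#' @param data A growth series (or data frame with `time`, `weight`).
#' @param family Model family name.
#' @return Named numeric vector of starting values on the natural scale.
#' @export
default_init <- function(data, family) {
  series <- as_growth_series(data)
  family <- canon_family(family)
  w <- series$weight
  t <- series$time
  if (diff(range(w)) < .Machine$double.eps^0.5 * max(w)) {
    rlang::abort("cannot initialize from a constant (degenerate) series.",
      class = "hyperbolastic_init_error")
  }
  M0 <- 1.05 * max(w)
  pos <- t > 0
  gamma0 <- {
    z <- -log((M0 - w[pos]) / M0)
    sl <- coef(lm(log(z) ~ log(t[pos])))[2]
    min(max(sl, 0.2), 8)
  }
  rate_scale <- function(y, g) {
    sl <- coef(lm(y ~ I(t^g)))[2]
    max(-sl, 1e-10)
  }
  switch(family,
    H1 = {
      d0 <- rate_scale(log((M0 - w) / w), 1)
      c(M = M0, delta = max(d0, 1e-4), theta = 0.001)
    },
    H2 = c(M = M0, delta = rate_scale(log((M0 - w) / w), gamma0), gamma = gamma0),
    H3 = c(M = M0, delta = rate_scale(log(M0 - w), gamma0), gamma = gamma0,
           theta = 0.001),
    gompertz = {
      co <- coef(lm(log(log(M0 / w)) ~ t))
      c0 <- min(co[2], -1e-4)
      c(b = min(-exp(co[1]), -1e-3), c = c0)
    },
    weibull = c(M = M0, beta = rate_scale(log(M0 - w), gamma0), gamma = gamma0))
}

# Multistart grid: the default init plus restarts over the time-power gamma
# (delta/beta re-derived per gamma), guarding against the ridge between the
# rate scale and the time power.
start_grid <- function(series, family) {
  base <- default_init(series, family)
  t <- series$time
  w <- series$weight
  M0 <- unname(base["M"])
  starts <- list(base)
  rate_scale <- function(y, g) max(-coef(lm(y ~ I(t^g)))[2], 1e-10)
  if (family == "H3") {
    for (g in c(1, 2, 3, 5, 7)) {
      starts <- c(starts, list(c(M = M0, delta = rate_scale(log(M0 - w), g),
        gamma = g, theta = 0.001)))
    }
  } else if (family == "weibull") {
    for (g in c(1, 2, 3, 5)) {
      starts <- c(starts, list(c(M = M0, beta = rate_scale(log(M0 - w), g),
        gamma = g)))
    }
  } else if (family == "H2") {
    for (g in c(0.5, 1, 2, 3)) {
      starts <- c(starts, list(c(M = M0, delta = rate_scale(log((M0 - w) / w), g),
        gamma = g)))
    }
  } else if (family == "H1") {
    for (d in c(0.02, 0.1)) {
      starts <- c(starts, list(c(M = M0, delta = d, theta = 0)))
    }
  } else if (family == "gompertz") {
    starts <- c(starts, list(c(b = -5, c = -0.02)))
  }
  starts
}

#' Fit a growth model by nonlinear least squares
#'
#' Estimates the free parameters of one model family from a growth series.
#' The scale constant alpha is not estimated: it is re-anchored at
#' `(t0, P0)` (by default the first observation) at every objective
#' evaluation, so every candidate curve passes exactly through that point.
#' Optimization uses bounded Levenberg-Marquardt ([minpack.lm::nls.lm()])
#' from several starting points; the lowest residual sum of squares wins,
#' with ties (difference below 1e-12) broken toward the smallest `gamma`.
#'
#' Standard errors are the usual linearization `s^2 (J'J)^-1` with
#' `s^2 = SSE/(n - k)` and `J` the Jacobian of the predictions with respect
#' to the free parameters at the optimum; 95% confidence limits use the
#' Student-t critical value on `n - k` degrees of freedom. When the Jacobian
#' condition number exceeds 1e8 the fit is flagged `rank_deficient` (a flat
#' ridge; the intervals are still reported, unclamped by the bounds).
#'
#' @param data A growth series or data frame with `time` and `weight`.
#' @param family One of `"H1"`, `"H2"`, `"H3"`, `"gompertz"`, `"weibull"`.
#' @param init Optional named starting vector (natural scale); replaces the
#'   multistart grid.
#' @param t0,P0 Anchoring point; defaults to the first observation.
#' @param n_jitter Number of additional randomly perturbed starts per grid
#'   start (0 disables jitter).
#' @param seed Seed for the jitter stream (ignored when `n_jitter = 0`).
#' @param control Passed to [minpack.lm::nls.lm.control()].
#' @return An object of class `growth_fit`; see [tidy()][tidy.growth_fit]
#'   and [glance()][glance.growth_fit].
#' @examples
#' fit <- fit_growth(ehrlich_tumor(), "H3")
#' tidy(fit)
#' glance(fit)
#' @export
fit_growth <- function(data, family, init = NULL, t0 = NULL, P0 = NULL,
                       n_jitter = 0, seed = 1,
                       control = minpack.lm::nls.lm.control(maxiter = 500,
                         ftol = 1e-15, ptol = 1e-15)) {
  series <- as_growth_series(data)
  family <- canon_family(family)
  k <- length(free_params(family))
  n <- nrow(series)
  if (n < k + 1) {
    rlang::abort(sprintf(
      "family %s has %d free parameters; need at least %d observations (got %d).",
      family, k, k + 1, n), class = "hyperbolastic_input_error")
  }
  t0 <- t0 %||% series$time[1]
  P0 <- P0 %||% series$weight[1]
  bounds <- fit_bounds(family, max(series$weight))

  starts <- if (is.null(init)) start_grid(series, family) else {
    list(init[free_params(family)])
  }
  if (n_jitter > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    jittered <- unlist(lapply(starts, function(s) {
      lapply(seq_len(n_jitter), function(i) s * exp(rnorm(length(s), 0, 0.1)))
    }), recursive = FALSE)
    starts <- c(starts, jittered)
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
  }

  resid_fn <- function(pint) {
    nat <- from_internal(family, pint)
    series$weight - eval_curve(family, nat, t0, P0, series$time)
  }
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

  best <- NULL
  best_sse <- Inf
  best_gamma <- Inf
  any_conv <- FALSE
  for (s in starts) {
    pint <- clip(to_internal(family, s), bounds$lower, bounds$upper)
    res <- tryCatch(
      minpack.lm::nls.lm(par = pint, lower = bounds$lower,
        upper = bounds$upper, fn = resid_fn, control = control),
      error = function(e) NULL)
    if (is.null(res)) next
    sse <- deviance(res)
    conv <- res$info %in% 1:3
    any_conv <- any_conv || conv
    g <- unname(coef(res)["gamma"] %||% NA_real_)
    better <- sse < best_sse - 1e-12 ||
      (abs(sse - best_sse) < 1e-12 && !is.na(g) && g < best_gamma)
    if (is.null(best) || better) {
      best <- res
      best_sse <- sse
      best_gamma <- if (is.na(g)) Inf else g
    }
  }
  if (is.null(best)) {
    rlang::abort("all optimizer starts failed.",
      class = "hyperbolastic_fit_error")
  }

  est <- from_internal(family, coef(best))
  # bounded families: clamp the log-scaled parameter's reported estimate at 0
  s <- internal_scaled(family)
  if (!is.null(s) && est[s] < 1e-14) est[s] <- 0
  params <- do.call(growth_params,
    c(list(family = family), as.list(est), list(t0 = t0, P0 = P0)))
  fitted <- predict(params, series$time)
  residuals <- series$weight - fitted
  sse <- sum(residuals^2)

  se <- wald_intervals(family, est, t0, P0, series, sse, k)

  structure(list(
    series = series, family = family, params = params,
    estimates = est, std_error = se$se, conf_low = se$lo, conf_high = se$hi,
    fitted = fitted, residuals = residuals, sse = sse,
    n = n, k = k, df = n - k,
    converged = best$info %in% 1:3 && any_conv,
    info = best$info, message = best$message,
    rank_deficient = se$rank_deficient, jac_cond = se$cond,
    t0 = t0, P0 = P0, n_starts = length(starts)),
    class = "growth_fit")
}

# Finite-difference Jacobian of predictions w.r.t. natural free parameters,
# then the linearized covariance s^2 (J'J)^-1 via SVD.
wald_intervals <- function(family, est, t0, P0, series, sse, k) {
  n <- nrow(series)
  # step is relative to the estimate (the curvature scale tracks the
  # parameter's own magnitude, e.g. 1/t^gamma for a tiny delta); the
  # absolute fallback applies only at an exact zero (bound-clamped case)
  scales <- c(M = 1, delta = 1e-6, gamma = 1, theta = 1e-4,
              b = 1, c = 0.01, beta = 1e-8)
  J <- vapply(seq_along(est), function(j) {
    h <- 6e-6 * if (abs(est[j]) > 0) abs(est[j]) else scales[[names(est)[j]]]
    up <- est; up[j] <- est[j] + h
    dn <- est; dn[j] <- est[j] - h
    # keep the perturbed point valid (sign constraints)
    if (names(est)[j] %in% c("b", "c") && up[j] >= 0) up[j] <- est[j]
    (eval_curve(family, up, t0, P0, series$time) -
       eval_curve(family, dn, t0, P0, series$time)) / (up[j] - dn[j])
  }, numeric(n))
  sv <- svd(J)
  d <- sv$d
  cond <- d[1] / d[k]
  dfl <- pmax(d, d[1] * 1e-14)
  s2 <- sse / (n - k)
  covm <- sv$v %*% diag(1 / dfl^2, k) %*% t(sv$v) * s2
  se <- sqrt(pmax(diag(covm), 0))
  names(se) <- names(est)
  tc <- qt(0.975, n - k)
  list(se = se, lo = est - tc * se, hi = est + tc * se,
    rank_deficient = cond > 1e8, cond = cond)
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit: %s, n = %d, anchored at (%g d, %g g)>\n",
    x$family, x$n, x$t0, x$P0))
  cat(sprintf("  SSE = %.6g, converged = %s%s\n", x$sse, x$converged,
    if (x$rank_deficient) ", rank-deficient Jacobian (flat ridge)" else ""))
  print(as.data.frame(tidy(x)), digits = 4)
  invisible(x)
}

#' Tidy a growth-model fit
#'
#' One row per free parameter: estimate, standard error, and 95%
#' Wald-t confidence limits (critical value `qt(0.975, n - k)`).
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    std.error = unname(x$std_error),
    conf.low = unname(x$conf_low),
    conf.high = unname(x$conf_high))
}

#' One-row fit summary
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return A tibble with the family, sample size, goodness-of-fit measures
#'   (SSE, residual mean square, R-squared, mean absolute relative error,
#'   Gaussian AIC) and convergence flags.
#' @export
glance.growth_fit <- function(x, ...) {
  obs <- x$series$weight
  tibble::tibble(
    family = x$family, nobs = x$n, k = x$k, df.residual = x$df,
    sse = x$sse,
    rms = rms_error(x$sse, x$n, x$k),
    sigma = sqrt(rms_error(x$sse, x$n, x$k)),
    r.squared = r_squared(obs, x$fitted),
    mare = mare(obs, x$fitted),
    aic = aic_gaussian(x$sse, x$n, x$k),
    converged = x$converged,
    rank_deficient = x$rank_deficient)
}

#' Predict from a fitted growth model
#'
#' @param object A `growth_fit`.
#' @param times Times (days); defaults to the fitted series' times.
#' @param ... Unused.
#' @return Predicted weights (grams).
#' @export
predict.growth_fit <- function(object, times = NULL, ...) {
  predict(object$params, times %||% object$series$time)
}

#' @export
residuals.growth_fit <- function(object, ...) object$residuals
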