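# Model families
#
# Five sigmoidal growth laws for tumor mass P(t), each with a closed-form
# curve, an analytic first and second derivative, and a rate-equation (ODE)
# form. The integration constant alpha is never free: it is anchored so the
# curve passes exactly through the first observation (t0, P0).
#
# Closed forms (t in days, P in grams):
#   H1       P(t) = M / (1 + a exp(-d t - th asinh t))
#   H2       P(t) = M / (1 + a asinh(exp(-d t^g)))
#   H3       P(t) = M - a exp(-d t^g - asinh(th t))
#   Gompertz P(t) = a exp(b exp(c t)),  b < 0, c < 0
#   Weibull  P(t) = M - a exp(-be t^g)
# with a (alpha) recomputed from the remaining parameters and (t0, P0).

FAMILIES <- c("H1", "H2", "H3", "gompertz", "weibull")

free_params <- function(family) {
  switch(family,
    H1 = c("M", "delta", "theta"),
    H2 = c("M", "delta", "gamma"),
    H3 = c("M", "delta", "gamma", "theta"),
    gompertz = c("b", "c"),
    weibull = c("M", "beta", "gamma"))
}

canon_family <- function(family) {
  m <- match(tolower(family), tolower(FAMILIES))
  if (is.na(m)) {
    rlang::abort(
      sprintf("unknown model family '%s'; choose one of %s.",
        family, paste(FAMILIES, collapse = ", ")),
      class = "hyperbolastic_input_error")
  }
  FAMILIES[m]
}

check_params <- function(family, p, t0, P0) {
  bad <- function(msg) rlang::abort(msg, class = "hyperbolastic_param_error")
  if (!is.finite(P0) || P0 <= 0) bad("P0 must be > 0 grams (non-positive P0).")
  if (!is.finite(t0) || t0 < 0) bad("t0 must be >= 0 days.")
  need <- free_params(family)
  miss <- setdiff(need, names(p)[!vapply(p, is.null, logical(1))])
  if (length(miss) > 0) {
    bad(sprintf("family %s needs parameter(s): %s.", family,
      paste(miss, collapse = ", ")))
  }
  p <- p[need]
  if (!all(vapply(p, function(x) is.numeric(x) && is.finite(x), logical(1)))) {
    bad("all parameters must be finite numbers.")
  }
  if ("M" %in% need && p$M <= P0) {
    bad(sprintf("carrying capacity M (%.4g) must exceed P0 (%.4g): M <= P0.", p$M, P0))
  }
  if ("gamma" %in% need && p$gamma <= 0) {
    bad("gamma must be > 0 (gamma <= 0).")
  }
  if (family == "gompertz" && (p$b >= 0 || p$c >= 0)) {
    bad("Gompertz requires b < 0 and c < 0.")
  }
  if (family == "weibull" && p$beta < 0) {
    bad("beta must be >= 0; the Weibull scale is parameterized with beta > 0.")
  }
  p
}

#' Anchor the scale constant alpha at the initial condition
#'
#' Each family's closed form contains an integration constant alpha. It is
#' never fitted: it is computed from the other parameters so that
#' `P(t0) == P0` holds exactly. The per-family formulas are
#' \describe{
#'   \item{H1}{`(M - P0)/P0 * exp(delta*t0 + theta*asinh(t0))`}
#'   \item{H2}{`(M - P0) / (P0 * asinh(exp(-delta*t0^gamma)))`}
#'   \item{H3}{`(M - P0) * exp(delta*t0^gamma + asinh(theta*t0))`}
#'   \item{Gompertz}{`P0 * exp(-b*exp(c*t0))`}
#'   \item{Weibull}{`(M - P0) * exp(beta*t0^gamma)`}
#' }
#'
#' @param family One of `"H1"`, `"H2"`, `"H3"`, `"gompertz"`, `"weibull"`.
#' @param params Named list/vector of the family's free parameters
#'   (see [growth_params()]).
#' @param t0,P0 Anchoring time (days) and weight (grams).
#' @return The scale value alpha (numeric scalar).
#' @examples
#' anchor_alpha("H1", list(M = 8.3, delta = 0.087, theta = -0.206), 9, 0.21)
#' @export
anchor_alpha <- function(family, params, t0, P0) {
  family <- canon_family(family)
  p <- check_params(family, as.list(params), t0, P0)
  switch(family,
    H1 = (p$M - P0) / P0 * exp(p$delta * t0 + p$theta * asinh(t0)),
    H2 = (p$M - P0) / (P0 * asinh(exp(-p$delta * t0^p$gamma))),
    H3 = (p$M - P0) * exp(p$delta * t0^p$gamma + asinh(p$theta * t0)),
    gompertz = P0 * exp(-p$b * exp(p$c * t0)),
    weibull = (p$M - P0) * exp(p$beta * t0^p$gamma))
}

#' Anchored model parameters
#'
#' Bundles a model family, its free parameters, the anchoring point
#' `(t0, P0)` and the derived scale `alpha` into a `growth_params` object
#' that [predict()][predict.growth_params], [growth_rate()],
#' [growth_acceleration()] and [integrate_rate_equation()] operate on.
#'
#' Free parameters by family (alpha is always derived, never supplied):
#' H1 `M, delta, theta`; H2 `M, delta, gamma`; H3 `M, delta, gamma, theta`;
#' Gompertz `b, c` (both negative, no carrying capacity M); Weibull
#' `M, beta, gamma`. `M` is the carrying capacity in grams; `gamma > 0`
#' accelerates the time scale; `theta` measures departure from a symmetric
#' sigmoid.
#'
#' @param family Model family name.
#' @param ... Named free parameters for that family.
#' @param t0,P0 Anchoring time (days) and weight (grams); the curve passes
#'   through this point exactly.
#' @return A list of class `growth_params`.
#' @examples
#' p <- growth_params("H3", M = 7.533, delta = 3.594e-9, gamma = 4.712,
#'   theta = 0.004, t0 = 9, P0 = 0.21)
#' predict(p, c(9, 40, 82))
#' @export
growth_params <- function(family, ..., t0, P0) {
  family <- canon_family(family)
  p <- check_params(family, list(...), t0, P0)
  alpha <- anchor_alpha(family, p, t0, P0)
  structure(
    list(family = family, pars = p, alpha = alpha, t0 = t0, P0 = P0),
    class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("<growth_params: %s, anchored at (t0 = %g d, P0 = %g g)>\n",
    x$family, x$t0, x$P0))
  cat("  ", paste(sprintf("%s = %.6g", names(x$pars), unlist(x$pars)),
    collapse = ", "), sprintf(", alpha = %.6g", x$alpha), "\n")
  invisible(x)
}

# t-domain guards. order 1 = velocity, 2 = acceleration; the t^(gamma-1) /
# t^(gamma-2) factors are singular at t = 0 for non-integer exponents.
check_times <- function(t, gamma = NULL, order = 0) {
  if (any(!is.finite(t)) || any(t < 0)) {
    rlang::abort("times must be finite and >= 0 days.",
      class = "hyperbolastic_domain_error")
  }
  if (!is.null(gamma) && any(t == 0)) {
    if (order >= 1 && gamma < 1) {
      rlang::abort("rate is singular at t = 0 when gamma < 1.",
        class = "hyperbolastic_domain_error")
    }
    if (order >= 2 && gamma < 2 && gamma != 1) {
      rlang::abort("acceleration is singular at t = 0 when gamma < 2 (gamma != 1).",
        class = "hyperbolastic_domain_error")
    }
  }
  invisible(t)
}

#' Evaluate the closed-form growth curve
#'
#' @param object A [growth_params()] object.
#' @param times Numeric vector of times (days, `>= 0`).
#' @param ... Unused.
#' @return Predicted weights (grams), one per time.
#' @export
predict.growth_params <- function(object, times, ...) {
  check_times(times)
  p <- object$pars
  a <- object$alpha
  t <- times
  switch(object$family,
    H1 = p$M / (1 + a * exp(-p$delta * t - p$theta * asinh(t))),
    H2 = p$M / (1 + a * asinh(exp(-p$delta * t^p$gamma))),
    H3 = p$M - a * exp(-p$delta * t^p$gamma - asinh(p$theta * t)),
    gompertz = a * exp(p$b * exp(p$c * t)),
    weibull = p$M - a * exp(-p$beta * t^p$gamma))
}

#' Analytic growth velocity dP/dt
#'
#' First derivative of the closed-form curve, in grams/day. For every family
#' this is the hand-differentiated closed form; [rate_ode_rhs()] gives the
#' same quantity through the family's rate equation, and the two are
#' algebraically identical (a property the test suite checks).
#'
#' @inheritParams predict.growth_params
#' @param params A [growth_params()] object.
#' @return Growth rates (grams/day), one per time.
#' @export
growth_rate <- function(params, times) {
  stopifnot(inherits(params, "growth_params"))
  p <- params$pars
  a <- params$alpha
  t <- times
  check_times(t, p$gamma, order = 1)
  switch(params$family,
    H1 = {
      E <- a * exp(-p$delta * t - p$theta * asinh(t))
      g <- p$delta + p$theta / sqrt(1 + t^2)
      p$M * E * g / (1 + E)^2
    },
    H2 = {
      u <- exp(-p$delta * t^p$gamma)
      D <- 1 + a * asinh(u)
      p$M * a * p$delta * p$gamma * t^(p$gamma - 1) * u /
        (sqrt(1 + u^2) * D^2)
    },
    H3 = {
      A <- a * exp(-p$delta * t^p$gamma - asinh(p$theta * t))
      A * (p$delta * p$gamma * t^(p$gamma - 1) +
             p$theta / sqrt(1 + p$theta^2 * t^2))
    },
    gompertz = {
      P <- a * exp(p$b * exp(p$c * t))
      P * p$b * p$c * exp(p$c * t)
    },
    weibull = {
      A <- a * exp(-p$beta * t^p$gamma)
      A * p$beta * p$gamma * t^(p$gamma - 1)
    })
}

#' Analytic growth acceleration d2P/dt2
#'
#' Second derivative of the closed-form curve, in grams/day^2. Its sign
#' change from + to - locates the inflection of P, i.e. the maximum of the
#' growth rate.
#'
#' @inheritParams growth_rate
#' @return Accelerations (grams/day^2), one per time.
#' @export
growth_acceleration <- function(params, times) {
  stopifnot(inherits(params, "growth_params"))
  p <- params$pars
  a <- params$alpha
  t <- times
  check_times(t, p$gamma, order = 2)
  switch(params$family,
    H1 = {
      P <- predict(params, t)
      g <- p$delta + p$theta / sqrt(1 + t^2)
      gp <- -p$theta * t * (1 + t^2)^(-3 / 2)
      rate <- P * (p$M - P) / p$M * g
      g * rate * (p$M - 2 * P) / p$M + P * (p$M - P) / p$M * gp
    },
    H2 = {
      g <- p$gamma
      u <- exp(-p$delta * t^g)
      up <- -p$delta * g * t^(g - 1) * u
      S <- sqrt(1 + u^2)
      D <- 1 + a * asinh(u)
      rate <- p$M * a * p$delta * g * t^(g - 1) * u / (S * D^2)
      term1 <- if (g == 1) rep(0, length(t)) else (g - 1) / t
      rate * (term1 - p$delta * g * t^(g - 1) - u * up / (1 + u^2) -
                2 * a * up / (S * D))
    },
    H3 = {
      A <- a * exp(-p$delta * t^p$gamma - asinh(p$theta * t))
      g <- p$delta * p$gamma * t^(p$gamma - 1) +
        p$theta / sqrt(1 + p$theta^2 * t^2)
      gp1 <- if (p$gamma == 1) 0 else
        p$delta * p$gamma * (p$gamma - 1) * t^(p$gamma - 2)
      gp <- gp1 - p$theta^3 * t * (1 + p$theta^2 * t^2)^(-3 / 2)
      A * (gp - g^2)
    },
    gompertz = {
      P <- a * exp(p$b * exp(p$c * t))
      h <- p$b * p$c * exp(p$c * t)
      P * h * (h + p$c)
    },
    weibull = {
      A <- a * exp(-p$beta * t^p$gamma)
      g <- p$beta * p$gamma * t^(p$gamma - 1)
      gp <- if (p$gamma == 1) 0 else
        p$beta * p$gamma * (p$gamma - 1) * t^(p$gamma - 2)
      A * (gp - g^2)
    })
}

#' Rate-equation right-hand side dP/dt = f(t, P)
#'
#' Evaluates the family's governing ordinary differential equation at an
#' arbitrary state `(t, P)`. With `P = predict(params, t)` this equals
#' [growth_rate()] exactly; the two code paths are independent, so their
#' agreement is a strong self-check on both.
#'
#' @inheritParams growth_rate
#' @param t Time (days).
#' @param P Weight (grams) at which to evaluate the right-hand side.
#' @return dP/dt (grams/day).
#' @export
rate_ode_rhs <- function(params, t, P) {
  stopifnot(inherits(params, "growth_params"))
  p <- params$pars
  a <- params$alpha
  check_times(t, p$gamma, order = 1)
  switch(params$family,
    H1 = P / p$M * (p$M - P) * (p$delta + p$theta / sqrt(1 + t^2)),
    H2 = a * p$delta * p$gamma * P^2 * t^(p$gamma - 1) *
      tanh((p$M - P) / (a * P)) / p$M,
    H3 = (p$M - P) * (p$delta * p$gamma * t^(p$gamma - 1) +
                        p$theta / sqrt(1 + p$theta^2 * t^2)),
    gompertz = p$c * P * log(P / a),
    weibull = (p$M - P) * p$beta * p$gamma * t^(p$gamma - 1))
}

#' Integrate the growth ODE numerically
#'
#' Solves the family's rate equation from the anchored initial condition
#' `(t0, P0)` with `deSolve::ode()` (lsoda) and returns the solution on the
#' requested grid. Because the closed forms are exact solutions of their
#' ODEs, the result must agree with [predict()][predict.growth_params] to
#' within the integration tolerance; the package uses this as a
#' transcription check on both forms.
#'
#' @inheritParams growth_rate
#' @param t_grid Increasing time grid (days) starting at or after `t0`.
#' @param rtol,atol Solver tolerances.
#' @return Weights (grams), one per grid point.
#' @export
integrate_rate_equation <- function(params, t_grid, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "growth_params"))
  if (length(t_grid) < 1 || any(diff(t_grid) <= 0)) {
    rlang::abort("t_grid must be non-empty and strictly increasing.",
      class = "hyperbolastic_input_error")
  }
  if (t_grid[1] < params$t0) {
    rlang::abort("t_grid must start at or after the anchoring time t0.",
      class = "hyperbolastic_input_error")
  }
  times <- t_grid
  prepend <- times[1] > params$t0
  if (prepend) times <- c(params$t0, times)
  if (length(times) == 1) return(params$P0)
  sol <- deSolve::ode(
    y = c(P = params$P0), times = times,
    func = function(t, y, parms) list(rate_ode_rhs(params, t, y[[1]])),
    rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    rlang::abort(
      paste0("ODE integration failed for family ", params$family,
        "; solver diagnostics: istate = ", attr(sol, "istate")[1]),
      class = "hyperbolastic_integration_error")
  }
  out <- sol[, "P"]
  if (prepend) out <- out[-1]
  unname(out)
}
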