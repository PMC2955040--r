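# Growth-dynamics analysis: where is the growth rate maximal, how large is
# it, and what do the velocity/acceleration profiles look like. The rate
# maximum (the inflection of P) is the headline kinetic summary used to
# compare treatment arms.

as_params <- function(object) {
  if (inherits(object, "growth_fit")) return(object$params)
  if (inherits(object, "growth_params")) return(object)
  rlang::abort("expected a growth_params or growth_fit object.",
    class = "hyperbolastic_input_error")
}

default_window <- function(object) {
  p <- as_params(object)
  if (inherits(object, "growth_fit")) {
    c(max(p$t0, 1e-6), 1.5 * max(object$series$time))
  } else {
    c(max(p$t0, 1e-6), NA_real_)
  }
}

#' Locate the maximum growth rate
#'
#' Finds the time at which the analytic growth velocity dP/dt peaks, by a
#' coarse grid scan (step 0.1 day) followed by golden-section refinement
#' ([stats::optimize()], tolerance 1e-6 day). Grid-then-refine is robust to
#' the flat, ridge-like rate profiles H3 can produce near its peak; an exact
#' plateau resolves to the smallest time. For a fitted model the default
#' search window is `[t0, 1.5 * max(observed time)]` — wide enough that a
#' late inflection (e.g. Gompertz) still lies in the interior.
#'
#' @param object A `growth_params` or `growth_fit`.
#' @param window Length-2 search window in days (`> 0`); required for bare
#'   parameter objects, defaulted for fits.
#' @param grid_step Coarse scan step (days).
#' @return A one-row tibble: `t_max` (days), `v_max` (grams/day), and
#'   `boundary` (`TRUE` when the rate is monotone on the window, so the
#'   maximum sits on an endpoint rather than at an interior peak).
#' @examples
#' fit <- fit_growth(ehrlich_tumor(), "gompertz")
#' max_growth_rate(fit)
#' @export
max_growth_rate <- function(object, window = NULL, grid_step = 0.1) {
  p <- as_params(object)
  window <- window %||% default_window(object)
  if (anyNA(window) || length(window) != 2 || window[1] <= 0 ||
      window[2] <= window[1]) {
    rlang::abort("need a valid search window (t_lo, t_hi), 0 < t_lo < t_hi.",
      class = "hyperbolastic_input_error")
  }
  grid <- seq(window[1], window[2], by = grid_step)
  if (grid[length(grid)] < window[2]) grid <- c(grid, window[2])
  v <- growth_rate(p, grid)
  i <- which.max(v)
  if (!is.finite(v[i]) || diff(range(v)) == 0) {
    return(tibble::tibble(t_max = grid[1], v_max = v[1], boundary = TRUE))
  }
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  boundary <- i == 1 || i == length(grid)
  if (boundary) {
    t_max <- grid[i]
    v_max <- v[i]
  } else {
    opt <- optimize(function(t) growth_rate(p, t), c(lo, hi),
      maximum = TRUE, tol = 1e-8)
    t_max <- opt$maximum
    v_max <- opt$objective
    # polish: the peak is a bracketed root of the analytic acceleration
    a_lo <- growth_acceleration(p, lo)
    a_hi <- growth_acceleration(p, hi)
    if (is.finite(a_lo) && is.finite(a_hi) && a_lo > 0 && a_hi < 0) {
      root <- stats::uniroot(function(t) growth_acceleration(p, t),
        c(lo, hi), tol = 1e-10)$root
      if (growth_rate(p, root) >= v_max) {
        t_max <- root
        v_max <- growth_rate(p, root)
      }
    }
    if (v[i] > v_max) { # plateau guard: never report worse than the scan
      t_max <- grid[i]
      v_max <- v[i]
    }
  }
  tibble::tibble(t_max = t_max, v_max = v_max, boundary = boundary)
}

#' Velocity and acceleration profiles
#'
#' Evaluates dP/dt and d2P/dt2 on a time grid and bundles them with the
#' rate-maximum summary.
#'
#' @inheritParams max_growth_rate
#' @param t_grid Evaluation grid (days, `> 0`); defaults to 400 points over
#'   the search window.
#' @return An object of class `growth_dynamics`: a list with `profile`
#'   (tibble `time`, `rate`, `acceleration`), `t_max`, `v_max`, `boundary`
#'   and `family`.
#' @export
growth_dynamics <- function(object, t_grid = NULL, window = NULL) {
  p <- as_params(object)
  window <- window %||% default_window(object)
  mx <- max_growth_rate(object, window = window)
  t_grid <- t_grid %||% seq(window[1], window[2], length.out = 400)
  profile <- tibble::tibble(
    time = t_grid,
    rate = growth_rate(p, t_grid),
    acceleration = growth_acceleration(p, t_grid))
  structure(list(profile = profile, t_max = mx$t_max, v_max = mx$v_max,
    boundary = mx$boundary, family = p$family),
    class = "growth_dynamics")
}

#' @export
print.growth_dynamics <- function(x, ...) {
  cat(sprintf(
    "<growth_dynamics: %s> max rate %.6g g/day on day %.4f%s (%d grid points)\n",
    x$family, x$v_max, x$t_max,
    if (x$boundary) " [window boundary]" else "", nrow(x$profile)))
  invisible(x)
}

#' Tidy a dynamics summary
#' @param x A `growth_dynamics` object.
#' @param ... Unused.
#' @return The profile tibble (`time`, `rate`, `acceleration`).
#' @export
tidy.growth_dynamics <- function(x, ...) x$profile

#' @rdname tidy.growth_dynamics
#' @export
glance.growth_dynamics <- function(x, ...) {
  tibble::tibble(family = x$family, t_max = x$t_max, v_max = x$v_max,
    boundary = x$boundary)
}

#' Compare treatment arms by their growth kinetics
#'
#' Summarizes several within-family fits (one per treatment arm) by carrying
#' capacity, maximum growth rate and its timing, and expresses each arm
#' relative to a reference arm: `v_ratio = v_max / v_max[reference]` and
#' `t_delay = t_max - t_max[reference]` (positive = later peak than the
#' reference; a reference with the latest peak simply yields negative
#' delays). Comparisons are within one model family by design; mixing
#' families is an error.
#'
#' @param fits List of `growth_fit` objects, one per arm, same family.
#' @param labels Arm names; defaults to the series labels or `arm1..armN`.
#' @param reference Index or label of the reference arm (default first).
#' @param window Optional shared search window for [max_growth_rate()].
#' @return A tibble with one row per arm: `arm`, `family`, `M`, `t_max`,
#'   `v_max`, `v_ratio`, `t_delay`.
#' @export
compare_arms <- function(fits, labels = NULL, reference = 1, window = NULL) {
  stopifnot(is.list(fits), length(fits) >= 2,
    all(vapply(fits, inherits, logical(1), "growth_fit")))
  fams <- vapply(fits, function(f) f$family, character(1))
  if (length(unique(fams)) != 1) {
    rlang::abort("arm comparisons are within-family: all fits must share one family.",
      class = "hyperbolastic_input_error")
  }
  labels <- labels %||% vapply(seq_along(fits), function(i) {
    attr(fits[[i]]$series, "label", exact = TRUE) %||% paste0("arm", i)
  }, character(1))
  if (is.character(reference)) reference <- match(reference, labels)
  if (is.na(reference) || reference < 1 || reference > length(fits)) {
    rlang::abort("reference arm not found.", class = "hyperbolastic_input_error")
  }
  rows <- purrr::map2_dfr(fits, labels, function(f, lab) {
    mx <- max_growth_rate(f, window = window)
    tibble::tibble(arm = lab, family = f$family,
      M = if ("M" %in% names(f$estimates)) unname(f$estimates["M"]) else NA_real_,
      t_max = mx$t_max, v_max = mx$v_max)
  })
  dplyr::mutate(rows,
    v_ratio = .data$v_max / rows$v_max[reference],
    t_delay = .data$t_max - rows$t_max[reference])
}
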