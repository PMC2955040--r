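# Synthetic growth-series generator. Emulates the design of the packaged
# tumor study: 18 observation times between day 9 and day 82, sigmoidal mean
# trajectories with carrying capacities around 7.5-8.3 g, maximum growth
# rates of roughly 0.15-0.45 g/day, and additive Gaussian measurement noise
# on the scale of the residual mean squares seen in practice (0.006-0.076
# g^2, i.e. sigma of about 0.08-0.28 g).

#' Default observation times for simulated series
#'
#' The 18 observation days (9 to 82) of the packaged case-study design.
#' @return Numeric vector of days.
#' @export
default_sim_times <- function() {
  c(9, 13, 17, 21, 29, 33, 37, 40, 43, 49, 55, 57, 60, 66, 72, 74, 78, 82)
}

#' Define a simulation scenario
#'
#' @param params A [growth_params()] object: the true generating curve.
#' @param times Observation times (days); default [default_sim_times()].
#' @param noise `"additive"` (homoscedastic Gaussian, in grams — the error
#'   structure unweighted least squares assumes) or `"proportional"`
#'   (Gaussian with standard deviation `noise_scale * mean`, as a
#'   robustness-study option).
#' @param noise_scale Noise standard deviation (grams, or fraction of the
#'   mean for proportional noise). Must be `>= 0`.
#' @param n_replicates Number of replicate series.
#' @param seed Root seed; per-replicate streams are derived from it, so a
#'   fixed seed gives byte-identical output.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(params, times = default_sim_times(),
                         noise = c("additive", "proportional"),
                         noise_scale = 0.08, n_replicates = 1, seed = 1) {
  stopifnot(inherits(params, "growth_params"))
  noise <- match.arg(noise)
  if (noise_scale < 0) {
    rlang::abort("noise_scale must be >= 0.", class = "hyperbolastic_input_error")
  }
  if (any(diff(times) <= 0) || any(times < 0)) {
    rlang::abort("times must be non-negative and strictly increasing.",
      class = "hyperbolastic_input_error")
  }
  structure(list(params = params, times = times, noise = noise,
    noise_scale = noise_scale, n_replicates = n_replicates,
    seed = as.integer(seed)), class = "sim_scenario")
}

#' Generate replicate growth series from a scenario
#'
#' Each replicate is `predict(true_params, times)` plus Gaussian noise,
#' truncated below at 0.01 g so weights stay positive (truncation rather
#' than rejection; at high noise this is a small positive bias at the
#' earliest time points). Per-replicate seeds are drawn once from the root
#' seed, so the output is deterministic and replicate `i` does not depend on
#' how many replicates follow it.
#'
#' @param scenario A [sim_scenario()].
#' @return A tibble with columns `replicate`, `time`, `weight`; pass a
#'   single replicate (or `dplyr::group_split()` output) to [fit_growth()].
#' @examples
#' p <- growth_params("H3", M = 7.5, delta = 1e-5, gamma = 3, theta = 0.004,
#'   t0 = 9, P0 = 0.21)
#' sim <- simulate_growth(sim_scenario(p, noise_scale = 0.08, n_replicates = 3))
#' @export
simulate_growth <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  mu <- predict(scenario$params, scenario$times)
  set.seed(scenario$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, scenario$n_replicates)
  purrr::map_dfr(seq_len(scenario$n_replicates), function(i) {
    set.seed(rep_seeds[i])
    eps <- rnorm(length(mu), 0, scenario$noise_scale)
    w <- switch(scenario$noise,
      additive = mu + eps,
      proportional = mu * (1 + eps))
    tibble::tibble(replicate = i, time = scenario$times,
      weight = pmax(w, 0.01))
  })
}

#' Calibrate an H3 curve to a target rate maximum
#'
#' Inverts the rate-maximum analysis: given a target peak growth rate
#' `v_max` at time `t_max`, returns H3 parameters (with `theta = 0`) whose
#' analytic rate attains exactly that maximum. With `theta = 0` the H3 rate
#' is `(M - P) * delta * gamma * t^(gamma - 1)`, whose interior maximum
#' requires `delta = (gamma - 1) / (gamma * t_max^gamma)`; `M` then follows
#' in closed form from the requested `v_max`. The time-power `gamma`
#' controls how peaked the rate profile is and is chosen by the caller.
#'
#' @param t_max Target time of the rate maximum (days, `> 0`).
#' @param v_max Target maximum rate (grams/day, `> 0`).
#' @param gamma Time-power (`> 1`), sets the sharpness of the peak.
#' @param t0,P0 Anchoring point.
#' @return A [growth_params()] object of family H3.
#' @export
calibrate_h3_arm <- function(t_max, v_max, gamma = 3, t0 = 9, P0 = 0.21) {
  stopifnot(t_max > 0, v_max > 0, gamma > 1)
  delta <- (gamma - 1) / (gamma * t_max^gamma)
  g_at <- delta * gamma * t_max^(gamma - 1)
  M <- P0 + v_max / (g_at * exp(delta * (t0^gamma - t_max^gamma)))
  growth_params("H3", M = M, delta = delta, gamma = gamma, theta = 0,
    t0 = t0, P0 = P0)
}

# Published kinetic summaries for the four treatment arms of the case study
# (peak growth rate in g/day and its day). Only the combined arm's raw
# series is available; the other three arms are synthetic stand-ins
# calibrated to these summaries.
arm_targets <- function() {
  tibble::tibble(
    arm = c("untreated", "IAA", "DMSO", "IAA+DMSO"),
    v_max = c(0.407303, 0.192412, 0.192293, 0.184104),
    t_max = c(19.6933, 37.3535, 46.9909, 57.2509))
}

#' Four-arm synthetic treatment scenario
#'
#' Builds the four-arm comparison the dynamics workflow is designed for:
#' untreated control, IAA only, DMSO only, and the combined IAA+DMSO arm.
#' The three arms without raw data are synthetic stand-ins whose true H3
#' curves are calibrated (via [calibrate_h3_arm()]) so that their peak rate
#' and its timing match the published arm summaries to well under 1%; the
#' combined arm uses the H3 fit to the packaged series itself. Gaussian
#' noise is then added per [simulate_growth()].
#'
#' @param seed Root seed for the noise streams.
#' @param noise_scale Additive noise SD in grams (0 gives the true curves).
#' @param times Observation days, shared by all arms.
#' @return A tibble with columns `arm`, `replicate`, `time`, `weight`.
#'   Attributes: `true_params` (named list of [growth_params()]) and
#'   `targets` (the calibration summaries).
#' @examples
#' arms <- four_arm_scenario(seed = 7, noise_scale = 0)
#' @export
four_arm_scenario <- function(seed = 1, noise_scale = 0.05,
                              times = default_sim_times()) {
  targets <- arm_targets()
  combined_fit <- fit_growth(ehrlich_tumor(), "H3")
  true_params <- list(
    untreated = calibrate_h3_arm(targets$t_max[1], targets$v_max[1], gamma = 3),
    IAA = calibrate_h3_arm(targets$t_max[2], targets$v_max[2], gamma = 3),
    DMSO = calibrate_h3_arm(targets$t_max[3], targets$v_max[3], gamma = 3.5),
    `IAA+DMSO` = combined_fit$params)
  out <- purrr::imap_dfr(true_params, function(p, arm) {
    sc <- sim_scenario(p, times = times, noise_scale = noise_scale,
      n_replicates = 1, seed = seed + match(arm, names(true_params)))
    dplyr::mutate(simulate_growth(sc), arm = arm, .before = 1)
  })
  attr(out, "true_params") <- true_params
  attr(out, "targets") <- targets
  out
}
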