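test_that("default starting values follow the documented heuristics", {
  s <- ehrlich_tumor()
  init <- default_init(s, "H3")
  expect_equal(unname(init["M"]), 1.05 * 7.35)
  expect_true(all(init[c("delta", "gamma", "theta")] > 0))
  flat <- data.frame(time = 1:5, weight = rep(2, 5))
  expect_error(default_init(flat, "H3"), "constant")
  expect_error(default_init(flat, "gompertz"), "constant")
})

test_that("noiseless synthetic data is recovered from perturbed starts", {
  true <- growth_params("H1", M = 8.3, delta = 0.09, theta = -0.2,
    t0 = 9, P0 = 0.21)
  sim <- simulate_growth(sim_scenario(true, noise_scale = 0, seed = 5))
  fit <- fit_growth(sim, "H1",
    init = c(M = 9.5, delta = 0.05, theta = 0.1),
    P0 = true$P0, t0 = true$t0)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates["M"]), 8.3, tolerance = 1e-4)
  expect_equal(unname(fit$estimates["delta"]), 0.09, tolerance = 1e-4)
  expect_lt(fit$sse, 1e-10)
})

test_that("each family reaches its optimum from the default multistart", {
  s <- ehrlich_tumor()
  # best attainable SSE per family, frozen from converged multistart runs
  best_sse <- c(H1 = 0.17923, H2 = 0.173951, H3 = 0.0809957,
    gompertz = 1.2165, weibull = 0.258251)
  for (fam in names(best_sse)) {
    fit <- fit_growth(s, fam)
    expect_true(fit$converged)
    expect_lte(fit$sse, best_sse[[fam]] * (1 + 1e-4))
  }
})

test_that("anchoring holds at every fit and residuals are orthogonal to the Jacobian", {
  s <- ehrlich_tumor()
  for (fam in c("H3", "gompertz")) {
    fit <- fit_growth(s, fam)
    expect_equal(predict(fit, fit$t0), fit$P0, tolerance = 1e-12)
    # gradient of SSE at the optimum: J' r == 0 (scaled)
    est <- fit$estimates
    J <- vapply(seq_along(est), function(j) {
      h <- 1e-6 * max(abs(est[j]), 1e-8)
      up <- est; up[j] <- up[j] + h
      dn <- est; dn[j] <- dn[j] - h
      f <- function(e) predict(do.call(growth_params, c(list(fit$family),
        as.list(e), list(t0 = fit$t0, P0 = fit$P0))), s$time)
      (f(up) - f(dn)) / (2 * h)
    }, numeric(fit$n))
    g <- drop(crossprod(J, fit$residuals))
    scaled <- abs(g) / (sqrt(colSums(J^2)) * sqrt(sum(fit$residuals^2)))
    expect_lt(max(scaled), 1e-6)
  }
})

test_that("confidence intervals use the Student-t convention on n - k df", {
  s <- ehrlich_tumor()
  fit <- fit_growth(s, "H3")
  td <- tidy(fit)
  tc <- qt(0.975, fit$n - fit$k)
  expect_equal(td$conf.high - td$estimate, tc * td$std.error)
  expect_equal(td$estimate - td$conf.low, tc * td$std.error)
  expect_true(all(td$conf.low < td$estimate & td$estimate < td$conf.high))
  # the printed interval for the H3 carrying capacity is reproduced by
  # estimate +/- t(0.975, 14) * SE: 2.1448 * 0.098 = 0.210
  expect_equal(qt(0.975, 14) * 0.098, 0.210, tolerance = 0.002)
  expect_equal(7.533 + qt(0.975, 14) * 0.098 * c(-1, 1), c(7.322, 7.744),
    tolerance = 5e-4)
})

test_that("refitted standard errors reproduce the published uncertainty", {
  s <- ehrlich_tumor()
  f3 <- fit_growth(s, "H3")
  expect_equal(unname(f3$std_error["M"]), 0.098, tolerance = 0.005)
  expect_equal(unname(f3$conf_low["M"]), 7.322, tolerance = 1e-3)
  expect_equal(unname(f3$conf_high["M"]), 7.744, tolerance = 1e-3)
  expect_true(f3$rank_deficient) # delta-gamma ridge: condition number > 1e8

  f1 <- fit_growth(s, "H1")
  expect_equal(unname(f1$conf_low["theta"]), -0.506, tolerance = 2e-3)
  expect_equal(unname(f1$conf_high["theta"]), 0.094, tolerance = 2e-3)
  expect_false(f1$rank_deficient)
})

test_that("fitting refuses series smaller than the parameter count", {
  tiny <- data.frame(time = c(1, 2, 3), weight = c(0.2, 0.5, 1.1))
  expect_error(fit_growth(tiny, "H3"), "at least 5 observations")
  expect_silent(fit_growth(tiny, "gompertz"))
})
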