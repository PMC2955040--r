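test_that("numeric rate maximum matches the Gompertz closed form", {
  fit <- fit_growth(ehrlich_tumor(), "gompertz")
  mx <- max_growth_rate(fit)
  b <- fit$estimates[["b"]]
  cc <- fit$estimates[["c"]]
  # the Gompertz rate peaks where the inner exponential term equals -1
  expect_equal(mx$t_max, log(-1 / b) / cc, tolerance = 1e-6)
  expect_false(mx$boundary)
})

test_that("H1 with theta = 0 is logistic: peak rate M*delta/4 at P = M/2", {
  p <- growth_params("H1", M = 8, delta = 0.1, theta = 0, t0 = 9, P0 = 0.21)
  mx <- max_growth_rate(p, window = c(1, 150))
  expect_equal(mx$v_max, 8 * 0.1 / 4, tolerance = 1e-6)
  expect_equal(predict(p, mx$t_max), 4, tolerance = 1e-6)
})

test_that("the refined maximum beats a dense grid and zeroes the acceleration", {
  for (fam in c("H3", "H2", "gompertz")) {
    p <- ref_params(fam)
    window <- c(9, 123)
    mx <- max_growth_rate(p, window = window)
    dense <- seq(window[1], window[2], by = 0.01)
    v_dense <- growth_rate(p, dense)
    expect_equal(mx$v_max, max(v_dense), tolerance = 1e-6)
    a <- growth_acceleration(p, mx$t_max)
    expect_lt(abs(a), 1e-6 * max(abs(growth_acceleration(p, dense))))
  }
})

test_that("profiles are unimodal with a single inflection for the published fits", {
  for (fam in all_families) {
    d <- growth_dynamics(ref_params(fam), t_grid = seq(10, 82, by = 0.25),
      window = c(9, 123))
    sign_changes <- sum(diff(sign(d$profile$acceleration)) != 0)
    expect_equal(sign_changes, 1)
    i_peak <- which.max(d$profile$rate)
    expect_true(all(diff(d$profile$rate[seq_len(i_peak)]) >= 0))
    expect_true(all(diff(d$profile$rate[i_peak:nrow(d$profile)]) <= 0))
  }
})

test_that("a monotone rate on the window is flagged as a boundary, not an error", {
  p <- ref_params("H3")
  mx <- max_growth_rate(p, window = c(10, 20)) # rate still rising at day 20
  expect_true(mx$boundary)
  expect_equal(mx$t_max, 20)
})

test_that("a degenerate zero-rate curve yields a flat flagged profile", {
  p <- growth_params("H3", M = 7.5, delta = 0, gamma = 2, theta = 0,
    t0 = 9, P0 = 0.21)
  d <- growth_dynamics(p, t_grid = seq(10, 80, by = 1), window = c(10, 80))
  expect_true(all(d$profile$rate == 0))
  expect_true(d$boundary)
})

test_that("arm comparison reports ratios and delays against the reference", {
  s <- ehrlich_tumor()
  f1 <- fit_growth(s, "H3")
  f2 <- fit_growth(s, "H3")
  cmp <- compare_arms(list(f1, f2), labels = c("a", "b"))
  expect_equal(cmp$v_ratio, c(1, 1))
  expect_equal(cmp$t_delay, c(0, 0))

  arms <- four_arm_scenario(seed = 3, noise_scale = 0)
  fits <- lapply(split(arms, factor(arms$arm, unique(arms$arm))),
    function(d) fit_growth(d, "H3"))
  cmp <- compare_arms(fits, labels = names(fits), reference = "untreated",
    window = c(9, 123))
  treated <- cmp[cmp$arm != "untreated", ]
  expect_true(all(treated$v_ratio < 0.5))
  expect_true(all(treated$t_delay > 0))
  # later-peaking reference arm gives negative delays, by sign convention
  cmp2 <- compare_arms(fits, labels = names(fits), reference = "IAA+DMSO",
    window = c(9, 123))
  expect_true(all(cmp2$t_delay[cmp2$arm != "IAA+DMSO"] < 0))

  fg <- fit_growth(s, "gompertz")
  expect_error(compare_arms(list(f1, fg)), "within-family")
})
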