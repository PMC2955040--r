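test_that("alpha anchoring makes every curve pass through (t0, P0)", {
  # closed-form substitution values, computed independently from the alpha
  # formulas (arcsinh(x) = log(x + sqrt(1 + x^2)))
  a_h3 <- (7.533 - 0.21) * exp(3.594e-9 * 9^4.712 +
    log(0.004 * 9 + sqrt(1 + (0.004 * 9)^2)))
  expect_equal(anchor_alpha("H3",
    list(M = 7.533, delta = 3.594e-9, gamma = 4.712, theta = 0.004),
    9, 0.21), a_h3)
  expect_equal(a_h3, 7.592, tolerance = 1e-4)

  a_h1 <- (8.298 - 0.21) / 0.21 * exp(0.087 * 9 - 0.206 * log(9 + sqrt(82)))
  expect_equal(anchor_alpha("H1",
    list(M = 8.298, delta = 0.087, theta = -0.206), 9, 0.21), a_h1)
  expect_equal(a_h1, 46.4, tolerance = 1e-3)

  set.seed(11)
  for (fam in all_families) {
    for (i in 1:5) {
      p <- random_params(fam)
      expect_equal(predict(p, p$t0), p$P0, tolerance = 1e-12)
    }
  }
})

test_that("invalid parameters are rejected with the violated constraint named", {
  expect_error(anchor_alpha("H3", list(M = 7.5, delta = 1e-9, gamma = 4.7,
    theta = 0.004), 9, -1), "non-positive P0")
  expect_error(anchor_alpha("H3", list(M = 0.1, delta = 1e-9, gamma = 4.7,
    theta = 0.004), 9, 0.21), "M <= P0")
  expect_error(anchor_alpha("H3", list(M = 7.5, delta = 1e-9, gamma = -1,
    theta = 0.004), 9, 0.21), "gamma <= 0")
  expect_error(growth_params("gompertz", b = 2, c = -0.02, t0 = 9, P0 = 0.21),
    "b < 0")
  expect_error(growth_params("weibull", M = 8, beta = -1e-6, gamma = 3,
    t0 = 9, P0 = 0.21), "beta")
  expect_error(growth_params("H1", M = 8, delta = 0.1, t0 = 9, P0 = 0.21),
    "theta")
})

test_that("published parameter sets reproduce the printed fitted values", {
  expect_equal(predict(ref_params("H3"), 82), 7.40, tolerance = 0.005)
  expect_equal(predict(ref_params("H1"), 40), 1.83, tolerance = 0.005)
  expect_equal(predict(ref_params("gompertz"), 82), 7.91, tolerance = 0.005)
  expect_equal(predict(ref_params("weibull"), 40), 1.86, tolerance = 0.005)
  # the whole Gompertz fitted column matches its printed values to the
  # printed 2-dp resolution
  tt <- ehrlich_tumor()$time
  printed_gompertz <- c(0.21, 0.32, 0.46, 0.64, 1.15, 1.48, 1.85, 2.17, 2.50,
    3.24, 4.04, 4.32, 4.74, 5.61, 6.49, 6.78, 7.35, 7.91)
  expect_lt(max(abs(predict(ref_params("gompertz"), tt) - printed_gompertz)),
    0.0105)
  expect_error(predict(ref_params("H3"), -2), "times must be")
})

test_that("analytic rate equals finite differences of the curve", {
  set.seed(21)
  h <- 1e-5
  for (fam in all_families) {
    for (i in 1:4) {
      p <- random_params(fam)
      for (t in c(15, 40, 70)) {
        fd <- (predict(p, t + h) - predict(p, t - h)) / (2 * h)
        expect_equal(growth_rate(p, t), fd, tolerance = 1e-6)
      }
    }
  }
})

test_that("rate equation and differentiated closed form agree (dual evaluation)", {
  set.seed(31)
  tt <- seq(9, 82, by = 0.5)
  for (fam in all_families) {
    for (i in 1:5) {
      p <- random_params(fam)
      P <- predict(p, tt)
      expect_equal(rate_ode_rhs(p, tt, P), growth_rate(p, tt),
        tolerance = 1e-9)
    }
  }
})

test_that("with theta = 0 the H3 rate degenerates to the Weibull rate form", {
  p3 <- growth_params("H3", M = 7.5, delta = 2e-5, gamma = 3, theta = 0,
    t0 = 9, P0 = 0.21)
  pw <- growth_params("weibull", M = 7.5, beta = 2e-5, gamma = 3,
    t0 = 9, P0 = 0.21)
  tt <- seq(9, 82, by = 1)
  expect_equal(growth_rate(p3, tt), growth_rate(pw, tt), tolerance = 1e-12)
  expect_equal(predict(p3, tt), predict(pw, tt), tolerance = 1e-12)
})

test_that("rate maximum of the published H3 curve matches the printed peak", {
  expect_equal(growth_rate(ref_params("H3"), 57.2509), 0.184104,
    tolerance = 1e-5)
  expect_equal(growth_acceleration(ref_params("H3"), 57.2509), 0,
    tolerance = 1e-6)
})

test_that("analytic acceleration matches second central differences", {
  set.seed(41)
  h <- 1e-3
  for (fam in all_families) {
    for (i in 1:4) {
      p <- random_params(fam)
      for (t in c(20, 40, 70)) {
        fd2 <- (predict(p, t + h) - 2 * predict(p, t) + predict(p, t - h)) / h^2
        a <- growth_acceleration(p, t)
        if (abs(fd2) > 1e-4) {
          expect_equal(a, fd2, tolerance = 1e-4)
        } else { # near the inflection: compare absolutely
          expect_lt(abs(a - fd2), 1e-6)
        }
      }
    }
  }
})

test_that("acceleration is positive early and negative late for the published fits", {
  tt <- seq(10, 82, by = 0.25)
  for (fam in all_families) {
    a <- growth_acceleration(ref_params(fam), tt)
    expect_gt(a[1], 0)
    expect_lt(a[length(a)], 0)
  }
})

test_that("rate and acceleration refuse the singular origin", {
  p <- growth_params("H3", M = 7.5, delta = 0.2, gamma = 0.5, theta = 0.004,
    t0 = 9, P0 = 0.21)
  expect_error(growth_rate(p, 0), "singular at t = 0")
  expect_error(growth_acceleration(p, 0), "singular")
  expect_silent(predict(p, 0))
})

test_that("numerical ODE solutions match the closed forms", {
  tt <- ehrlich_tumor()$time
  for (fam in all_families) {
    p <- ref_params(fam)
    expect_equal(integrate_rate_equation(p, tt), predict(p, tt),
      tolerance = 1e-6)
  }
  set.seed(51)
  for (fam in c("H1", "H2", "H3")) {
    for (i in 1:5) {
      p <- random_params(fam)
      grid <- seq(9, 82, length.out = 40)
      expect_equal(integrate_rate_equation(p, grid), predict(p, grid),
        tolerance = 1e-6)
    }
  }
  p <- ref_params("H3")
  expect_equal(integrate_rate_equation(p, 9), 0.21)
  expect_error(integrate_rate_equation(p, c(5, 9)), "start at or after")
  expect_error(integrate_rate_equation(p, c(10, 10)), "strictly increasing")
})

test_that("curves are monotone and bounded under the stated conditions", {
  set.seed(61)
  tt <- seq(0, 100, by = 0.5)
  for (i in 1:6) {
    p1 <- random_params("H1", monotone = TRUE) # delta > 0, theta >= 0
    w <- predict(p1, tt)
    expect_true(all(diff(w) >= -1e-12))
    expect_true(all(w > 0 & w < p1$pars$M))

    p3 <- random_params("H3") # delta, gamma, theta >= 0 by construction
    w3 <- predict(p3, seq(p3$t0, 120, by = 0.5))
    expect_true(all(diff(w3) >= -1e-12))
    expect_true(all(w3 >= p3$P0 - 1e-12 & w3 < p3$pars$M))

    p2 <- random_params("H2")
    w2 <- predict(p2, tt)
    expect_true(all(w2 > 0 & w2 <= p2$pars$M))
    # strictly below M until exp(-delta * t^gamma) underflows to zero
    unsaturated <- exp(-p2$pars$delta * tt^p2$pars$gamma) > 1e-15
    expect_true(all(w2[unsaturated] < p2$pars$M))
  }
})
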