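# Reference parameter sets: the published least-squares estimates for the
# combined-treatment Ehrlich carcinoma series, anchored at its first
# observation (day 9, 0.21 g). Used as known-good inputs for the model
# algebra; the fitting tests re-estimate them from the data.
ref_params <- function(family) {
  switch(family,
    H1 = growth_params("H1", M = 8.298, delta = 0.087, theta = -0.206,
      t0 = 9, P0 = 0.21),
    H2 = growth_params("H2", M = 8.223, delta = 0.055, gamma = 1.088,
      t0 = 9, P0 = 0.21),
    H3 = growth_params("H3", M = 7.533, delta = 3.594e-9, gamma = 4.712,
      theta = 0.004, t0 = 9, P0 = 0.21),
    gompertz = growth_params("gompertz", b = -5.418, c = -0.025,
      t0 = 9, P0 = 0.21),
    weibull = growth_params("weibull", M = 8.024, beta = 8.579e-7,
      gamma = 3.399, t0 = 9, P0 = 0.21))
}

all_families <- c("H1", "H2", "H3", "gompertz", "weibull")

# Published fitted-value column of the H3 model on the case-study series
# (rounded to 2 dp in the source).
h3_fitted_column <- c(0.21, 0.33, 0.46, 0.59, 0.96, 1.21, 1.53, 1.83, 2.18,
  3.04, 4.08, 4.45, 5.00, 6.01, 6.78, 6.97, 7.24, 7.40)

# Random valid parameter draws for property-style tests. Scale parameters
# are drawn so that the exponent delta * t^gamma spans O(1) over the
# observation horizon (t <= 82), mimicking realistic sigmoid shapes.
random_params <- function(family, monotone = FALSE) {
  t0 <- 9
  P0 <- runif(1, 0.1, 0.5)
  M <- runif(1, 5, 10)
  switch(family,
    H1 = growth_params("H1", M = M, delta = runif(1, 0.03, 0.15),
      theta = if (monotone) runif(1, 0, 0.3) else runif(1, -0.2, 0.3),
      t0 = t0, P0 = P0),
    H2 = growth_params("H2", M = M, delta = runif(1, 0.01, 0.1),
      gamma = runif(1, 0.6, 2), t0 = t0, P0 = P0),
    H3 = {
      g <- runif(1, 1, 5)
      growth_params("H3", M = M, delta = runif(1, 1, 4) / 82^g, gamma = g,
        theta = runif(1, 0, 0.01), t0 = t0, P0 = P0)
    },
    gompertz = growth_params("gompertz", b = runif(1, -8, -2),
      c = runif(1, -0.05, -0.015), t0 = t0, P0 = P0),
    weibull = {
      g <- runif(1, 1, 5)
      growth_params("weibull", M = M, beta = runif(1, 1, 4) / 82^g,
        gamma = g, t0 = t0, P0 = P0)
    })
}
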