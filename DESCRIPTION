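Package: hyperbolastic
Title: Hyperbolastic and Classical Sigmoidal Models of Tumor Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the hyperbolastic growth models H1, H2 and H3 alongside the
    Gompertz and Weibull curves to time series of tumor mass, by nonlinear
    least squares with the integration constant anchored at the first
    observation. Provides Wald-t standard errors and confidence intervals,
    model-comparison statistics (AIC, residual mean square, R-squared, mean
    absolute relative error), growth-dynamics summaries (maximum growth rate
    and its timing from the analytic velocity and acceleration), multi-arm
    treatment comparisons, and a calibrated synthetic-data generator for
    simulation studies. Ships the solid Ehrlich carcinoma series under
    combined iodoacetate/dimethylsulfoxide treatment as a worked case study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
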