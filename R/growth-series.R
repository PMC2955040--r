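#' Construct a growth series
#'
#' A growth series is an ordered set of (time, weight) observations for one
#' experimental arm: time in days, tumor mass in grams. It is the fitting
#' target for every model in the package. The constructor validates the
#' invariants all downstream code relies on: strictly increasing non-negative
#' times, strictly positive weights, and at least two observations.
#'
#' @param data A data frame with one row per observation.
#' @param time,weight Column names (tidy-eval) holding the observation times
#'   in days and tumor weights in grams. Default to `time` and `weight`.
#' @param label Optional free-text label for the arm (e.g. a treatment name).
#'
#' @return A tibble of class `growth_series` with columns `time` and `weight`
#'   and a `label` attribute.
#' @examples
#' growth_series(data.frame(time = c(1, 5, 9), weight = c(0.2, 0.8, 1.9)))
#' @export
growth_series <- function(data, time = time, weight = weight, label = NULL) {
  stopifnot(is.data.frame(data))
  out <- tibble::tibble(
    time = as.numeric(dplyr::pull(data, {{ time }})),
    weight = as.numeric(dplyr::pull(data, {{ weight }}))
  )
  validate_growth_series(out)
  attr(out, "label") <- label %||% attr(data, "label", exact = TRUE)
  class(out) <- c("growth_series", class(tibble::tibble()))
  out
}

#' Coerce to a growth series
#'
#' @param x A data frame with `time` and `weight` columns, or an existing
#'   `growth_series`.
#' @param label Optional arm label; kept from `x` when omitted.
#' @return A validated `growth_series` tibble.
#' @export
as_growth_series <- function(x, label = NULL) {
  if (inherits(x, "growth_series") && is.null(label)) {
    validate_growth_series(x)
    return(x)
  }
  if (!all(c("time", "weight") %in% names(x))) {
    rlang::abort("`x` must have `time` and `weight` columns.",
      class = "hyperbolastic_input_error")
  }
  growth_series(x, label = label)
}

validate_growth_series <- function(x) {
  t <- x$time
  w <- x$weight
  if (anyNA(t) || anyNA(w) || !all(is.finite(t)) || !all(is.finite(w))) {
    rlang::abort("times and weights must be finite and non-missing.",
      class = "hyperbolastic_input_error")
  }
  if (length(t) < 2) {
    rlang::abort("a growth series needs at least 2 observations.",
      class = "hyperbolastic_input_error")
  }
  if (any(t < 0)) {
    rlang::abort("times must be >= 0 days.", class = "hyperbolastic_input_error")
  }
  if (any(diff(t) <= 0)) {
    bad <- which(diff(t) <= 0)[1] + 1
    rlang::abort(
      sprintf("times must be strictly increasing (violated at row %d); refusing to sort silently.", bad),
      class = "hyperbolastic_input_error")
  }
  if (any(w <= 0)) {
    rlang::abort("weights must be > 0 grams.", class = "hyperbolastic_input_error")
  }
  invisible(x)
}

#' Read / write a growth series as two-column CSV
#'
#' The on-disk interchange format is a plain CSV with header `time,weight`
#' (days, grams).
#'
#' @param file Path to a CSV file.
#' @param label Optional arm label attached on read.
#' @return `read_growth_series()` returns a `growth_series`;
#'   `write_growth_series()` returns `file` invisibly.
#' @export
read_growth_series <- function(file, label = NULL) {
  df <- readr::read_csv(file, col_types = readr::cols(
    time = readr::col_double(), weight = readr::col_double()))
  growth_series(df, label = label)
}

#' @rdname read_growth_series
#' @param x A `growth_series` (or coercible data frame).
#' @export
write_growth_series <- function(x, file) {
  x <- as_growth_series(x)
  readr::write_csv(tibble::tibble(time = x$time, weight = x$weight), file)
  invisible(file)
}

#' Solid Ehrlich carcinoma series, combined IAA + DMSO treatment
#'
#' The packaged case-study data: mean weight (grams) of solid Ehrlich
#' carcinoma in mice under a combined iodoacetate (IAA) and dimethylsulfoxide
#' (DMSO) treatment, observed at 18 time points from day 9 to day 82. This is
#' the series the README and vignette analyses, and the default input for
#' [reproduce_analysis()].
#'
#' @return A `growth_series` with 18 rows, labelled `"IAA+DMSO"`.
#' @examples
#' ehrlich_tumor()
#' @export
ehrlich_tumor <- function() {
  path <- system.file("extdata", "ehrlich_iaa_dmso.csv",
    package = "hyperbolastic", mustWork = TRUE)
  read_growth_series(path, label = "IAA+DMSO")
}
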