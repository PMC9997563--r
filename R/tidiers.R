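# broom-style accessors for fitted objects.

#' Tidy a standard curve
#'
#' @param x An `fw_standard_curve`.
#' @param ... Ignored.
#' @return Tibble with one row per coefficient (`term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`).
#' @method tidy fw_standard_curve
#' @export
tidy.fw_standard_curve <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' One-row summary of a standard curve fit
#'
#' @param x An `fw_standard_curve`.
#' @param ... Ignored.
#' @return Tibble with `slope`, `intercept`, `r.squared`, `signal_kind`,
#'   `nobs`.
#' @method glance fw_standard_curve
#' @export
glance.fw_standard_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r.squared = x$r_squared,
         signal_kind = x$signal_kind, nobs = x$n)
}

#' Tidy windowed test results
#'
#' @param x An `fw_window_tests` tibble.
#' @param ... Ignored.
#' @return A plain tibble (the results are already tidy).
#' @method tidy fw_window_tests
#' @export
tidy.fw_window_tests <- function(x, ...) {
  as_tibble(x)
}
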