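# Group-level behavioral statistics: loess trend smoothing, windowed
# two-sided rank-sum tests, Benjamini-Hochberg adjustment.

#' Default 10-minute comparison windows
#'
#' Half-open `[start, end)` windows in minutes: 15-25, 25-35, 35-45, 45-55.
#'
#' @return List of length-2 numeric vectors `c(start_min, end_min)`.
#' @export
feeding_windows <- function() {
  list(c(15, 25), c(25, 35), c(35, 45), c(45, 55))
}

#' Smooth a time series with locally weighted regression
#'
#' Fits a loess curve (span as a fraction of the data, default 0.25) over the
#' time axis and evaluates it on a regular grid.
#'
#' @param points Data frame with columns `time` (minutes) and `value`.
#' @param span Smoothing span, fraction of the data in (0, 1\]; default 0.25.
#' @param n_grid Number of grid points for evaluation (default 100).
#' @param degree Local polynomial degree (default 2, the loess default).
#' @return Tibble of class `fw_trend` with columns `time` and `fitted`;
#'   attributes `span` and `degree`.
#' @export
smooth_trend <- function(points, span = 0.25, n_grid = 100, degree = 2) {
  points <- as_tibble(points)
  stopifnot(all(c("time", "value") %in% names(points)))
  if (nrow(points) < 10) abort("smooth_trend needs at least 10 points")
  if (!(span > 0 && span <= 1)) abort("span must be in (0, 1]")
  fit <- loess(value ~ time, data = points, span = span, degree = degree,
               family = "gaussian")
  grid <- seq(min(points$time), max(points$time), length.out = n_grid)
  out <- tibble(time = grid, fitted = as.numeric(predict(fit, newdata =
                                                           tibble(time = grid))))
  class(out) <- c("fw_trend", class(out))
  attr(out, "span") <- span
  attr(out, "degree") <- degree
  out
}

#' Two-sided unpaired rank-sum (Mann-Whitney U) test
#'
#' Compares two independent samples. In `"auto"` mode the exact null
#' distribution is enumerated when `n1 + n2 <= 12` and there are no ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used. Groups of flies are independent, so the unpaired
#' rank-sum test is the appropriate member of the Wilcoxon family. When every
#' pooled value is identical the test is degenerate and `p = 1` is returned
#' (no evidence of a shift).
#'
#' @param x,y Numeric samples (both nonempty).
#' @param mode `"auto"`, `"exact"` or `"approximate"`.
#' @return One-row tibble: `statistic` (U for `x`), `p_value` (two-sided),
#'   `n1`, `n2`, `method`.
#' @export
rank_sum_test <- function(x, y, mode = c("auto", "exact", "approximate")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) abort("both samples must be nonempty")
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(mode,
    auto = (length(x) + length(y) <= 12) && !has_ties,
    exact = TRUE,
    approximate = FALSE
  )
  if (exact && has_ties) {
    warn("ties present; falling back to the normal approximation")
    exact <- FALSE
  }
  u <- unname(wilcox.test(x, y, exact = FALSE)$statistic)
  if (length(unique(c(x, y))) == 1) {
    # all pooled values tied: zero-variance null, no evidence either way
    return(tibble(statistic = u, p_value = 1, n1 = length(x), n2 = length(y),
                  method = "degenerate"))
  }
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  p <- res$p.value
  if (is.nan(p)) p <- 1
  tibble(statistic = unname(res$statistic), p_value = min(p, 1),
         n1 = length(x), n2 = length(y),
         method = if (exact) "exact" else "normal approximation")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a family of p-values for false discovery rate: sorted ascending,
#' `p_adj(i) = min over j >= i of (m/j) * p(j)`, capped at 1, returned in the
#' input order.
#'
#' @param p Numeric vector of raw p-values, each in (0, 1\].
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Windowed rank-sum comparisons between two groups
#'
#' For each time window (default the 10-minute windows 15-25, 25-35, 35-45,
#' 45-55 min, half-open `[start, end)`), compares a behavioral measure
#' between two groups of flies with a two-sided rank-sum test, then adjusts
#' the raw p-values across the windows of this comparison with
#' Benjamini-Hochberg. By default each fly contributes one value per window
#' (the mean of its raw per-frame or per-interval measure over the window),
#' which avoids pseudo-replication across frames; `unit = "per_frame"` pools
#' raw records instead.
#'
#' @param a,b Data frames with columns `fly` (identifier), `time_min` and
#'   `value` — one row per raw record (frame or interval) per fly.
#' @param windows List of `c(start_min, end_min)` windows.
#' @param unit `"per_fly"` (default) or `"per_frame"`.
#' @param measure Optional label copied into the result.
#' @return Tibble of class `fw_window_tests`: `measure`, `window_start_min`,
#'   `window_end_min`, `n1`, `n2`, `statistic`, `p_raw`, `p_adj`, `missing`.
#'   Windows with no data in either group are reported with `missing = TRUE`
#'   (never dropped silently) and excluded from the adjustment family.
#' @export
windowed_tests <- function(a, b, windows = feeding_windows(),
                           unit = c("per_fly", "per_frame"),
                           measure = "value") {
  unit <- match.arg(unit)
  pick <- function(d, w) {
    d <- as_tibble(d)
    d <- d[d$time_min >= w[1] & d$time_min < w[2], ]
    if (nrow(d) == 0) return(numeric(0))
    if (unit == "per_fly") {
      v <- d |> group_by(.data$fly) |>
        summarise(v = mean(.data$value), .groups = "drop")
      v$v
    } else {
      d$value
    }
  }
  rows <- purrr::map(windows, function(w) {
    xa <- pick(a, w)
    xb <- pick(b, w)
    if (length(xa) == 0 || length(xb) == 0) {
      return(tibble(window_start_min = w[1], window_end_min = w[2],
                    n1 = length(xa), n2 = length(xb),
                    statistic = NA_real_, p_raw = NA_real_, missing = TRUE))
    }
    t <- rank_sum_test(xa, xb)
    tibble(window_start_min = w[1], window_end_min = w[2],
           n1 = t$n1, n2 = t$n2, statistic = t$statistic,
           p_raw = t$p_value, missing = FALSE)
  })
  out <- bind_rows(rows)
  out$p_adj <- NA_real_
  ok <- !out$missing
  if (any(ok)) out$p_adj[ok] <- bh_adjust(out$p_raw[ok])
  out <- mutate(out, measure = measure, .before = 1)
  class(out) <- c("fw_window_tests", class(out))
  out
}

#' Write window test results to CSV
#'
#' Columns
#' `measure,window_start_min,window_end_min,n1,n2,statistic,p_raw,p_adj,missing`.
#'
#' @param tests An `fw_window_tests` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_window_tests <- function(tests, path) {
  readr::write_csv(as_tibble(tests), path, progress = FALSE)
  invisible(path)
}
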