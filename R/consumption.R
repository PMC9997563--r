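# Dye-based food-intake quantification: linear standard curves and inverse
# estimation for absorbance (630 nm, excreta dye) and fluorescence (in-body
# dye) plate readings.

#' Fit a linear standard curve
#'
#' Ordinary least-squares fit of `signal = slope * known_amount + intercept`
#' over a calibration series. Linear calibration is the standard for
#' Beer-Lambert-range dye assays; a warning is raised when the fit explains
#' less than 95% of the signal variance.
#'
#' @param points Data frame with columns `known_amount` (food volume in uL or
#'   dye mass) and `signal` (absorbance at 630 nm in AU, or RFU).
#' @param signal_kind `"absorbance_630"` or `"fluorescence"`.
#' @return Object of class `fw_standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `signal_kind`, `n`, plus the underlying `lm` fit and the
#'   calibration points.
#' @export
fit_standard_curve <- function(points,
                               signal_kind = c("absorbance_630",
                                               "fluorescence")) {
  signal_kind <- match.arg(signal_kind)
  points <- as_tibble(points)
  stopifnot(all(c("known_amount", "signal") %in% names(points)))
  if (any(points$known_amount < 0) || any(!is.finite(points$signal))) {
    abort("known_amount must be >= 0 and signals finite")
  }
  if (length(unique(points$known_amount)) < 2) {
    abort("calibration needs at least 2 distinct known amounts")
  }
  fit <- lm(signal ~ known_amount, data = points)
  r2 <- summary(fit)$r.squared
  if (is.na(r2)) r2 <- 1  # exact fit with zero residual variance
  if (r2 < 0.95) {
    warn(sprintf("standard curve r^2 = %.3f < 0.95; check calibration series",
                 r2))
  }
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = r2, signal_kind = signal_kind, n = nrow(points),
         fit = fit, points = points),
    class = "fw_standard_curve"
  )
}

#' @export
print.fw_standard_curve <- function(x, ...) {
  cat(sprintf(
    "<fw_standard_curve> %s: signal = %.6g * amount + %.6g (r^2 = %.4f, n = %d)\n",
    x$signal_kind, x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Invert plate readings to amount of food per fly
#'
#' Estimates the amount of ingested food per fly from each well's signal via
#' the inverse of the standard curve:
#' `amount = (signal - blank - intercept) / slope / flies_per_well`.
#' Negative inversions (signal below the curve at zero) are clamped to 0 with
#' a warning. If a `feeding_duration_h` column is present, a
#' `rate_per_hour` column is added via [per_hour_rate()].
#'
#' @param readings Data frame with columns `well`, `signal`,
#'   `flies_per_well`; optionally `feeding_duration_h`.
#' @param curve An `fw_standard_curve`.
#' @param blank Optional blank signal subtracted from all wells before
#'   inversion (default 0).
#' @return The input tibble with an `amount_per_fly` column (and
#'   `rate_per_hour` when duration is available).
#' @export
quantify <- function(readings, curve, blank = 0) {
  stopifnot(inherits(curve, "fw_standard_curve"))
  if (curve$slope == 0) abort("standard curve is not invertible (slope 0)")
  readings <- as_tibble(readings)
  stopifnot(all(c("well", "signal", "flies_per_well") %in% names(readings)))
  amount_total <- (readings$signal - blank - curve$intercept) / curve$slope
  neg <- amount_total < 0
  if (any(neg)) {
    warn(sprintf("%d well(s) with signal below the blank/intercept clamped to 0: %s",
                 sum(neg), paste(readings$well[neg], collapse = ", ")))
    amount_total[neg] <- 0
  }
  readings$amount_per_fly <- amount_total / readings$flies_per_well
  if ("feeding_duration_h" %in% names(readings)) {
    readings$rate_per_hour <- per_hour_rate(readings$amount_per_fly,
                                            readings$feeding_duration_h)
  }
  readings
}

#' Consumption rate per hour
#'
#' Converts a total consumed amount over a feeding period to an hourly rate,
#' e.g. 0.10 uL per fly over 2 h is 0.05 uL per hour.
#'
#' @param total Amount consumed (uL or dye-equivalent units).
#' @param duration_h Feeding duration in hours (> 0).
#' @return `total / duration_h`.
#' @examples
#' per_hour_rate(0.10, 2) # 0.05
#' @export
per_hour_rate <- function(total, duration_h) {
  if (any(duration_h <= 0)) abort("duration_h must be > 0")
  total / duration_h
}

#' Exclude dead or damaged flies from plate readings
#'
#' Dead and damaged flies (scored visually, carried by the plate map `alive`
#' flag) are excluded before quantification. The exclusion report is attached
#' as the `"excluded"` attribute and retrievable with [excluded_wells()].
#'
#' @param readings Data frame with a `well` column.
#' @param platemap Plate map tibble from [read_platemap()] (columns `well`,
#'   `alive`).
#' @return Tibble of retained (alive) readings; attribute `"excluded"` is a
#'   tibble `well`, `reason`.
#' @export
exclude_dead <- function(readings, platemap) {
  readings <- as_tibble(readings)
  unknown <- setdiff(readings$well, platemap$well)
  if (length(unknown) > 0) {
    abort(paste0("wells not in plate map: ", paste(unknown, collapse = ", ")))
  }
  alive <- platemap$alive[match(readings$well, platemap$well)]
  excluded <- tibble(well = readings$well[!alive],
                     reason = "dead or damaged")
  out <- readings[alive, ]
  attr(out, "excluded") <- excluded
  out
}

#' Exclusion report of a filtered readings table
#'
#' @param readings Output of [exclude_dead()].
#' @return Tibble `well`, `reason` (zero rows when nothing was excluded).
#' @export
excluded_wells <- function(readings) {
  ex <- attr(readings, "excluded")
  if (is.null(ex)) tibble(well = character(), reason = character()) else ex
}

#' Read a plate-reader CSV export
#'
#' Expected header `well,signal` (additional columns are kept).
#'
#' @param path CSV path.
#' @return Tibble.
#' @export
read_plate_readings <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("well", "signal"), names(x))
  if (length(missing) > 0) {
    abort(paste0("plate readings missing columns: ",
                 paste(missing, collapse = ", ")), class = "fw_schema_error")
  }
  x
}

#' Read a calibration-series CSV
#'
#' Expected header `known_amount,signal`.
#'
#' @param path CSV path.
#' @return Tibble usable by [fit_standard_curve()].
#' @export
read_calibration <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("known_amount", "signal"), names(x))
  if (length(missing) > 0) {
    abort(paste0("calibration series missing columns: ",
                 paste(missing, collapse = ", ")), class = "fw_schema_error")
  }
  x
}
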