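# Per-frame behavioral measures and 2-minute interval aggregation.

#' Per-frame food-interaction flag
#'
#' The flag is 1 iff the fly silhouette is fully enclosed in the image region
#' of the food circle: every silhouette pixel lies within `r` pixels
#' (Euclidean) of the circle center. A frame without a detected silhouette
#' scores 0.
#'
#' @param pixels n x 2 matrix of silhouette pixel positions (0-based x, y),
#'   or `NULL` when no silhouette was found.
#' @param circle Food circle as a list or one-row data frame with `cx`, `cy`,
#'   `r`.
#' @return Integer 0 or 1.
#' @export
food_interaction_flag <- function(pixels, circle) {
  if (is.null(pixels) || nrow(pixels) == 0) return(0L)
  if (!isTRUE(circle$r > 0)) abort("food circle radius must be > 0")
  d2 <- (pixels[, 1] - circle$cx)^2 + (pixels[, 2] - circle$cy)^2
  as.integer(all(d2 <= circle$r^2))
}

#' Euclidean inter-frame distance between centroids
#'
#' Distance in image pixels between the silhouette centroid of the current
#' frame and that of the previous frame. If either centroid is absent (fly
#' not found) the distance contributes 0 — the missing frame stays in the
#' record so gap burden can be audited downstream.
#'
#' @param prev,cur Length-2 numeric vectors `c(x, y)`; `NULL` or `NA`
#'   components mean absent.
#' @return Distance in pixels (0 when either centroid is absent).
#' @export
interframe_distance <- function(prev, cur) {
  if (is.null(prev) || is.null(cur) || anyNA(prev) || anyNA(cur)) return(0)
  sqrt(sum((cur - prev)^2))
}

# Vectorized per-well distance stream: distance assigned to the current
# frame; frame 0 and frames adjacent to a missing detection contribute 0.
distance_stream <- function(cx, cy) {
  n <- length(cx)
  if (n == 0) return(numeric(0))
  d <- c(0, sqrt(diff(cx)^2 + diff(cy)^2))
  d[is.na(d)] <- 0
  d
}

#' Aggregate per-frame measures into nonoverlapping intervals
#'
#' For each well and each nonoverlapping interval (default 2 min) aligned to
#' frame 0, computes the fraction of frames whose food-interaction flag is 1
#' and the cumulative inter-frame distance over the frames falling in the
#' interval. Frames without a detection keep flag 0 and distance 0 but stay
#' in the denominator, so intervals remain comparable in `n_frames`. A
#' trailing interval shorter than `interval_s` is emitted with its true frame
#' count and `partial = TRUE`.
#'
#' @param detections An `fw_detections` tibble (or any tibble with columns
#'   `frame`, `well`, `cx`, `cy`, `food_flag`).
#' @param fps Frames per second; defaults to the `fps` attribute of
#'   `detections`.
#' @param interval_s Interval length in seconds (default 120).
#' @return Tibble of class `fw_intervals` with columns `well`, `interval`,
#'   `start_s`, `n_frames`, `food_fraction`, `distance_px`, `partial`.
#' @export
summarize_intervals <- function(detections, fps = NULL, interval_s = 120) {
  if (is.null(fps)) fps <- attr(detections, "fps")
  if (is.null(fps) || !isTRUE(fps > 0)) abort("fps must be > 0")
  det <- as_tibble(detections)
  if (nrow(det) == 0) {
    out <- tibble(well = character(), interval = integer(),
                  start_s = numeric(), n_frames = integer(),
                  food_fraction = numeric(), distance_px = numeric(),
                  partial = logical())
    class(out) <- c("fw_intervals", class(out))
    attr(out, "interval_s") <- interval_s
    return(out)
  }
  frames_per_interval <- interval_s * fps
  out <- det |>
    arrange(.data$well, .data$frame) |>
    group_by(.data$well) |>
    mutate(
      dist = distance_stream(.data$cx, .data$cy),
      interval = as.integer(.data$frame %/% frames_per_interval)
    ) |>
    group_by(.data$well, .data$interval) |>
    summarise(
      start_s = min(.data$frame) / fps,
      n_frames = dplyr::n(),
      food_fraction = mean(.data$food_flag),
      distance_px = sum(.data$dist),
      .groups = "drop"
    ) |>
    mutate(
      start_s = .data$interval * interval_s,
      partial = .data$n_frames < frames_per_interval
    ) |>
    arrange(.data$well, .data$interval)
  class(out) <- c("fw_intervals", class(out))
  attr(out, "fps") <- fps
  attr(out, "interval_s") <- interval_s
  out
}

#' Normalize interval distances to relative units
#'
#' Divides every per-interval cumulative distance by the maximum
#' per-interval distance, so the most active interval maps to 1. The
#' normalization scope is by default the whole compared set (global maximum
#' across wells); `scope = "per_fly"` normalizes each well by its own
#' maximum. An all-zero distance set is returned unchanged (no division).
#'
#' @param summaries An `fw_intervals` tibble.
#' @param scope `"global"` (default) or `"per_fly"`.
#' @return The input with an added `distance_rel` column in \[0, 1\].
#' @export
normalize_distances <- function(summaries, scope = c("global", "per_fly")) {
  scope <- match.arg(scope)
  norm <- function(d) {
    m <- max(d)
    if (m <= 0) d else d / m
  }
  if (scope == "global") {
    summaries$distance_rel <- norm(summaries$distance_px)
    summaries
  } else {
    out <- summaries |>
      group_by(.data$well) |>
      mutate(distance_rel = norm(.data$distance_px)) |>
      ungroup()
    class(out) <- class(summaries)
    out
  }
}

#' Write interval summaries to CSV
#'
#' Columns `well,interval,start_s,n_frames,food_fraction,distance_px,partial`.
#'
#' @param summaries An `fw_intervals` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(summaries, path) {
  readr::write_csv(as_tibble(summaries), path, progress = FALSE)
  invisible(path)
}
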