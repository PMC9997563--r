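# Feeding-bout denoising: run-length encoding of the per-frame
# food-interaction stream and the two-pass noise-removal rule that merges it
# into feeding / non-feeding blocks.

#' Real-valued frame count of one feeding burst
#'
#' A starved fly takes about 7 sips per feeding burst at about 0.13 s per
#' sip, i.e. 0.91 s per burst; at 30 fps that is 27.3 frames. The integer
#' threshold used downstream for the minimum feeding run is the floor of this
#' value.
#'
#' @param sips Sips per feeding burst (default 7).
#' @param sip_s Duration of one sip in seconds (default 0.13).
#' @param fps Frames per second (default 30).
#' @return Frames per burst, real-valued (`fps * sips * sip_s`).
#' @examples
#' burst_frame_threshold() # 27.3
#' @export
burst_frame_threshold <- function(sips = 7, sip_s = 0.13, fps = 30) {
  stopifnot(sips >= 0, sip_s >= 0, fps >= 0)
  fps * sips * sip_s
}

#' Bout-denoising parameters
#'
#' Bundles the thresholds of the feeding-bout noise rule. `min_on_frames`
#' defaults to `floor(burst_frame_threshold(sips_per_burst, sip_duration_s,
#' fps))` — 27 frames at the defaults — the minimum run of consecutive
#' food-interaction frames counted as time near the food; `min_off_frames`
#' (default 10) is the minimum run counted as time away from food.
#'
#' @param sips_per_burst,sip_duration_s,fps Burst microstructure and frame
#'   rate used to derive `min_on_frames`.
#' @param min_on_frames,min_off_frames Integer thresholds in frames.
#' @return List of class `fw_bout_params`.
#' @export
bout_params <- function(sips_per_burst = 7, sip_duration_s = 0.13, fps = 30,
                        min_on_frames = floor(burst_frame_threshold(
                          sips_per_burst, sip_duration_s, fps)),
                        min_off_frames = 10) {
  stopifnot(sips_per_burst > 0, sip_duration_s > 0, fps > 0,
            min_on_frames > 0, min_off_frames > 0)
  structure(list(sips_per_burst = sips_per_burst,
                 sip_duration_s = sip_duration_s, fps = fps,
                 min_on_frames = as.integer(min_on_frames),
                 min_off_frames = as.integer(min_off_frames)),
            class = "fw_bout_params")
}

check_flags <- function(flags) {
  if (!all(flags %in% c(0L, 1L))) abort("flags must be binary (0/1)")
  as.integer(flags)
}

#' Run-length encode a binary flag series
#'
#' Aggregates the per-frame stream into blocks of consecutive frames in the
#' same state.
#'
#' @param flags Integer/logical vector over \{0, 1\}.
#' @return Tibble with columns `state`, `start_frame` (0-based),
#'   `length_frames`; consecutive rows alternate state and lengths sum to
#'   `length(flags)`.
#' @export
run_length_encode <- function(flags) {
  flags <- check_flags(flags)
  if (length(flags) == 0) {
    return(tibble(state = integer(), start_frame = integer(),
                  length_frames = integer()))
  }
  r <- rle(flags)
  tibble(
    state = r$values,
    start_frame = cumsum(c(0L, head(r$lengths, -1L))),
    length_frames = r$lengths
  )
}

#' Decode a run table back to a flag series
#'
#' Inverse of [run_length_encode()].
#'
#' @param runs Tibble with `state` and `length_frames`.
#' @return Integer flag vector.
#' @export
run_length_decode <- function(runs) {
  rep(as.integer(runs$state), runs$length_frames)
}

#' Denoise a food-interaction flag series
#'
#' Two deterministic passes over the run-length encoding:
#' 1. gap closing — every 0-run shorter than `min_off_frames` lying between
#'    two 1-runs is flipped to 1 (brief departures inside a feeding visit);
#' 2. short-run removal — every remaining 1-run shorter than `min_on_frames`
#'    is flipped to 0 (contacts shorter than one feeding burst).
#'
#' The output has no interior 0-run shorter than `min_off_frames` and no
#' 1-run shorter than `min_on_frames`; leading/trailing 0-runs are never
#' flipped. One application of the two passes is a fixed point (idempotent).
#'
#' @param flags Binary flag vector.
#' @param params An `fw_bout_params` (defaults: 27-frame minimum feeding run,
#'   10-frame minimum away run).
#' @return Denoised integer flag vector, same length.
#' @export
denoise_flags <- function(flags, params = bout_params()) {
  flags <- check_flags(flags)
  if (length(flags) == 0) return(flags)
  # pass 1: close interior 0-gaps shorter than min_off_frames
  r <- rle(flags)
  n <- length(r$values)
  if (n >= 3) {
    interior <- seq_len(n)[-c(1, n)]
    close <- interior[r$values[interior] == 0L &
                        r$lengths[interior] < params$min_off_frames]
    r$values[close] <- 1L
  }
  flags <- inverse.rle(r)
  # pass 2: remove 1-runs shorter than min_on_frames
  r <- rle(flags)
  drop <- r$values == 1L & r$lengths < params$min_on_frames
  r$values[drop] <- 0L
  inverse.rle(r)
}

#' Tabulate feeding bouts from a flag series
#'
#' Denoises the series with [denoise_flags()] and returns one row per
#' feeding block, with times in seconds via the frame rate.
#'
#' @param flags Binary flag vector.
#' @param params An `fw_bout_params`.
#' @param denoise Set `FALSE` if `flags` is already denoised.
#' @return Tibble of class `fw_bouts` with columns `bout`, `start_s`,
#'   `duration_s`.
#' @export
bout_table <- function(flags, params = bout_params(), denoise = TRUE) {
  if (denoise) flags <- denoise_flags(flags, params)
  runs <- run_length_encode(flags)
  on <- runs[runs$state == 1L, ]
  out <- tibble(
    bout = seq_len(nrow(on)),
    start_s = on$start_frame / params$fps,
    duration_s = on$length_frames / params$fps
  )
  class(out) <- c("fw_bouts", class(out))
  attr(out, "fps") <- params$fps
  out
}

#' Feeding bouts for every well of a detections table
#'
#' @param detections An `fw_detections` tibble.
#' @param params An `fw_bout_params`; its `fps` should match the recording.
#' @return Tibble of class `fw_bouts` with columns `well`, `bout`, `start_s`,
#'   `duration_s`.
#' @export
session_bouts <- function(detections, params = bout_params()) {
  det <- as_tibble(detections) |> arrange(.data$well, .data$frame)
  out <- det |>
    group_by(.data$well) |>
    group_modify(function(d, key) bout_table(d$food_flag, params)) |>
    ungroup()
  class(out) <- c("fw_bouts", class(out))
  attr(out, "fps") <- params$fps
  out
}
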