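# Synthetic multi-well sessions with ground truth: two-state (roam/at-food)
# behavior, flat-shaded ellipse rendering on a uniform NIR-like backlight,
# sub-fly-size speck noise.

#' Simulation parameters for synthetic sessions
#'
#' Defaults emulate the recording conditions of the assay: 30 fps
#' acquisition, one dark fly blob per well on a bright backlight, feeding
#' bursts of 7 sips of 0.13 s when burst mode is on, and speck noise strictly
#' smaller than the detection size filter.
#'
#' @param n_wells Number of wells (1-96); wells take the first `n_wells`
#'   plate coordinates and are placed on the image grid by their plate row
#'   and column.
#' @param well_px Side of the square well region in pixels (default 160).
#' @param fly_axes Semi-axes of the fly ellipse in pixels (default `c(7, 4)`).
#' @param fly_darkness Intensity drop of the fly silhouette below background,
#'   0-255 scale (default 80).
#' @param background Backlight intensity (default 200).
#' @param p_roam_food,p_food_roam Per-frame transition probabilities of the
#'   two-state behavior chain (defaults 1/1800 and 1/900: mean roaming
#'   sojourn 60 s, mean feeding visit 30 s at 30 fps, stationary at-food
#'   occupancy 1/3).
#' @param step_sd Roaming random-walk step standard deviation, px/frame.
#' @param food_radius Food circle radius in pixels (default 24).
#' @param burst_mode When `TRUE`, at-food periods are chopped into feeding
#'   bursts of `sips_per_burst * sip_duration_s` seconds separated by
#'   `burst_gap_frames` non-interaction frames, to exercise bout denoising.
#' @param sips_per_burst,sip_duration_s Burst microstructure (defaults 7 and
#'   0.13 s).
#' @param burst_gap_frames Gap between bursts in frames (default 5, below the
#'   10-frame away-from-food threshold so denoising merges the bursts back).
#' @param fps Frames per second (default 30).
#' @param duration_s Session duration in seconds (default 120).
#' @param speck_rate Expected specks per well per frame (default 0).
#' @param speck_max_area Maximum speck area in pixels (default 4, below the
#'   default 8 px detection size filter).
#' @return List of class `fw_sim_params`.
#' @export
sim_params <- function(n_wells = 8, well_px = 160, fly_axes = c(7, 4),
                       fly_darkness = 80, background = 200,
                       p_roam_food = 1 / 1800, p_food_roam = 1 / 900,
                       step_sd = 3, food_radius = 24,
                       burst_mode = FALSE, sips_per_burst = 7,
                       sip_duration_s = 0.13, burst_gap_frames = 5,
                       fps = 30, duration_s = 120,
                       speck_rate = 0, speck_max_area = 4) {
  stopifnot(
    n_wells >= 1, n_wells <= 96,
    p_roam_food >= 0, p_roam_food <= 1,
    p_food_roam >= 0, p_food_roam <= 1,
    fps > 0, duration_s > 0, well_px >= 16,
    all(fly_axes > 0), fly_darkness > 0, background > 0,
    food_radius > 0, speck_rate >= 0, speck_max_area >= 1
  )
  if (2 * max(fly_axes) + 4 >= well_px) {
    abort("fly blob larger than the well")
  }
  if (food_radius <= max(fly_axes) + 2) {
    abort("food circle too small to fully enclose the fly blob")
  }
  structure(as.list(environment()), class = "fw_sim_params")
}

# Wall/margin constants of the synthetic arena grid.
.fw_wall_px <- 4L
.fw_margin_px <- 2L

#' Build the arena layout of a synthetic session
#'
#' Wells are axis-aligned squares placed by their plate coordinates; the food
#' circle sits at the bottom center of each well, as the feeding port does.
#'
#' @param params An `fw_sim_params`.
#' @return An `fw_layout`.
#' @export
synthetic_layout <- function(params) {
  ids <- plate_wells()[seq_len(params$n_wells)]
  row <- match(substr(ids, 1, 1), LETTERS)
  col <- as.integer(substring(ids, 2))
  w <- params$well_px
  x0 <- .fw_margin_px + (col - 1) * (w + .fw_wall_px)
  y0 <- .fw_margin_px + (row - 1) * (w + .fw_wall_px)
  corners <- purrr::map2(x0, y0, function(a, b) {
    m <- rbind(c(a, b), c(a + w - 1, b), c(a + w - 1, b + w - 1),
               c(a, b + w - 1))
    colnames(m) <- c("x", "y")
    m
  })
  r <- params$food_radius
  food <- tibble(
    well = ids,
    cx = x0 + w / 2,
    cy = y0 + w - 1 - r - 4,
    r = r
  )
  arena_layout(
    wells = tibble(well = ids, corners = corners),
    food = food,
    frame_width = max(x0) + w + .fw_margin_px,
    frame_height = max(y0) + w + .fw_margin_px,
    fps = params$fps,
    n_wells = params$n_wells
  )
}

# Alternating geometric sojourns of the two-state chain; distributionally
# identical to per-frame Bernoulli transitions. Returns a run table
# (state 0 = roam, 1 = at_food).
sim_state_runs <- function(n_frames, p_rf, p_fr) {
  occ <- if (p_rf + p_fr == 0) 0 else p_rf / (p_rf + p_fr)
  state <- if (runif(1) < occ) 1L else 0L
  states <- integer(0)
  lengths <- integer(0)
  total <- 0L
  while (total < n_frames) {
    p <- if (state == 1L) p_fr else p_rf
    len <- if (p <= 0) n_frames - total else rgeom(1L, p) + 1L
    len <- min(len, n_frames - total)
    states <- c(states, state)
    lengths <- c(lengths, len)
    total <- total + len
    state <- 1L - state
  }
  list(states = states, lengths = lengths)
}

# Fold a free random walk into [lo, hi] by reflection (triangle wave).
reflect_fold <- function(z, lo, hi) {
  w <- hi - lo
  y <- (z - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

#' Simulate ground-truth behavior for a synthetic session
#'
#' Each well hosts one fly following a two-state Markov chain (roam /
#' at-food). While roaming the centroid performs a reflected Gaussian random
#' walk inside the well; while at the food it jitters inside the food circle,
#' close enough to the center that the whole blob stays enclosed. The raw
#' per-frame food-interaction flag equals the at-food state, optionally
#' chopped into feeding bursts (`burst_mode`).
#'
#' @param params An `fw_sim_params`.
#' @param seed Integer seed; mandatory (no implicit randomness).
#' @param layout Optional precomputed [synthetic_layout()].
#' @param positions Set `FALSE` to skip centroid generation (states and flags
#'   only), e.g. for large statistical simulations.
#' @return List of class `fw_ground_truth`: `truth` (tibble `frame`, `well`,
#'   `x`, `y`, `state`, `flag_raw`), `bouts` (tibble `well`, `start_s`,
#'   `duration_s` of true at-food periods), `layout`.
#' @export
simulate_behavior <- function(params, seed, layout = synthetic_layout(params),
                              positions = TRUE) {
  if (missing(seed) || is.null(seed)) abort("seed is required")
  set.seed(seed)
  n <- as.integer(round(params$duration_s * params$fps))
  e <- max(params$fly_axes) + 1  # inset keeping the whole blob inside
  per_well <- purrr::map(seq_len(params$n_wells), function(wi) {
    poly <- layout$wells$corners[[wi]]
    food <- layout$food[wi, ]
    runs <- sim_state_runs(n, params$p_roam_food, params$p_food_roam)
    states <- rep(runs$states, runs$lengths)
    x <- rep(NA_real_, n)
    y <- rep(NA_real_, n)
    if (positions) {
      lo_x <- min(poly[, 1]) + e; hi_x <- max(poly[, 1]) - e
      lo_y <- min(poly[, 2]) + e; hi_y <- max(poly[, 2]) - e
      max_r <- food$r - max(params$fly_axes) - 1
      pos <- c(runif(1, lo_x, hi_x), runif(1, lo_y, hi_y))
      at <- 0L
      for (k in seq_along(runs$states)) {
        len <- runs$lengths[k]
        idx <- at + seq_len(len)
        if (runs$states[k] == 1L) {
          # at food: jitter around the circle center, radially clamped
          jx <- rnorm(len, 0, 1.5); jy <- rnorm(len, 0, 1.5)
          rad <- sqrt(jx^2 + jy^2)
          shrink <- pmin(1, max_r / pmax(rad, 1e-12))
          x[idx] <- food$cx + jx * shrink
          y[idx] <- food$cy + jy * shrink
        } else {
          sx <- cumsum(rnorm(len, 0, params$step_sd)) + pos[1]
          sy <- cumsum(rnorm(len, 0, params$step_sd)) + pos[2]
          x[idx] <- reflect_fold(sx, lo_x, hi_x)
          y[idx] <- reflect_fold(sy, lo_y, hi_y)
        }
        pos <- c(x[idx[len]], y[idx[len]])
        at <- at + len
      }
    }
    flags <- states
    if (params$burst_mode) {
      flags <- burstify_flags(runs, params)
    }
    on <- runs$states == 1L
    starts <- cumsum(c(0L, head(runs$lengths, -1L)))
    list(
      truth = tibble(frame = 0:(n - 1L), well = layout$wells$well[wi],
                     x = x, y = y,
                     state = rep(c("roam", "at_food")[runs$states + 1L],
                                 runs$lengths),
                     flag_raw = as.integer(flags)),
      bouts = tibble(well = layout$wells$well[wi],
                     start_s = starts[on] / params$fps,
                     duration_s = runs$lengths[on] / params$fps)
    )
  })
  structure(
    list(
      truth = bind_rows(purrr::map(per_well, "truth")),
      bouts = bind_rows(purrr::map(per_well, "bouts")),
      layout = layout
    ),
    class = "fw_ground_truth"
  )
}

# Chop at-food runs into bursts: `on` frames of interaction followed by a
# short gap, repeated; roam runs stay 0.
burstify_flags <- function(runs, params) {
  on_len <- max(1L, round(params$sips_per_burst * params$sip_duration_s *
                            params$fps))
  gap <- params$burst_gap_frames
  unlist(purrr::map2(runs$states, runs$lengths, function(s, len) {
    if (s == 0L) return(integer(len))
    pattern <- rep(c(1L, 0L), times = c(on_len, gap))
    rep(pattern, length.out = len)
  }), use.names = FALSE)
}

# Render one frame: copy the background template and stamp each fly ellipse
# (and any specks) into its well.
render_frame <- function(template, truth_row_x, truth_row_y, layout, params) {
  fr <- template
  a <- params$fly_axes[1]; b <- params$fly_axes[2]
  for (wi in seq_along(truth_row_x)) {
    cx <- truth_row_x[wi]; cy <- truth_row_y[wi]
    px <- floor(cx - a):ceiling(cx + a)
    py <- floor(cy - b):ceiling(cy + b)
    gx <- rep(px, each = length(py))
    gy <- rep(py, times = length(px))
    inside <- ((gx - cx) / a)^2 + ((gy - cy) / b)^2 <= 1
    fr[cbind(gy[inside] + 1L, gx[inside] + 1L)] <-
      params$background - params$fly_darkness
  }
  fr
}

add_specks <- function(fr, layout, params) {
  offsets <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(2, 0), c(0, 2))
  for (wi in seq_len(nrow(layout$wells))) {
    if (runif(1) >= params$speck_rate) next
    poly <- layout$wells$corners[[wi]]
    s <- sample.int(params$speck_max_area, 1)
    ox <- round(runif(1, min(poly[, 1]) + 3, max(poly[, 1]) - 3))
    oy <- round(runif(1, min(poly[, 2]) + 3, max(poly[, 2]) - 3))
    pts <- offsets[seq_len(s), , drop = FALSE]
    fr[cbind(oy + pts[, 2] + 1L, ox + pts[, 1] + 1L)] <-
      params$background - params$fly_darkness
  }
  fr
}

#' Generate a full synthetic session
#'
#' Simulates behavior, renders every frame (dark ellipse per well on a
#' uniform backlight, plus optional speck noise), and either returns the
#' frames in memory or writes a session directory: `frames/frame_%05d.png`,
#' `layout.json`, `platemap.csv`, `truth.csv`, `true_bouts.csv`.
#'
#' @param params An `fw_sim_params`.
#' @param seed Integer seed (mandatory).
#' @param dir Session directory to write; `NULL` keeps frames in memory
#'   (suitable only for short sessions).
#' @return List of class `fw_session`: `layout`, `truth`, `bouts`,
#'   `platemap`, and `frames` (list of matrices) or `dir`/`frames_dir`
#'   (paths) when `dir` is given.
#' @export
generate_session <- function(params, seed, dir = NULL) {
  if (missing(seed) || is.null(seed)) abort("seed is required")
  gt <- simulate_behavior(params, seed = seed)
  layout <- gt$layout
  n <- as.integer(round(params$duration_s * params$fps))
  template <- matrix(params$background, nrow = layout$frame_height,
                     ncol = layout$frame_width)
  # truth is stacked by well (well varies slowest); reshape to [frame, well]
  tr <- gt$truth
  xs <- matrix(tr$x, ncol = params$n_wells)
  ys <- matrix(tr$y, ncol = params$n_wells)

  ids <- layout$wells$well
  platemap <- tibble(
    well = ids,
    sex = rep(c("female", "male"), length.out = length(ids)),
    pretreatment = rep(c("starved", "fed"), each = 2,
                       length.out = length(ids)),
    diet_kcal = rep(c(100, 400), length.out = length(ids)),
    flies_per_well = 1L,
    alive = TRUE
  )

  write_out <- !is.null(dir)
  frames <- if (write_out) NULL else vector("list", n)
  if (write_out) {
    frames_dir <- file.path(dir, "frames")
    dir.create(frames_dir, recursive = TRUE, showWarnings = FALSE)
  }
  for (fi in seq_len(n)) {
    fr <- render_frame(template, xs[fi, ], ys[fi, ], layout, params)
    if (params$speck_rate > 0) fr <- add_specks(fr, layout, params)
    if (write_out) {
      png::writePNG(fr / 255,
                    file.path(frames_dir, sprintf("frame_%05d.png", fi - 1L)))
    } else {
      frames[[fi]] <- fr
    }
  }
  out <- list(layout = layout, truth = gt$truth, bouts = gt$bouts,
              platemap = platemap, params = params, seed = seed)
  if (write_out) {
    save_layout(layout, file.path(dir, "layout.json"))
    write_platemap(platemap, file.path(dir, "platemap.csv"))
    readr::write_csv(gt$truth, file.path(dir, "truth.csv"), progress = FALSE)
    readr::write_csv(gt$bouts, file.path(dir, "true_bouts.csv"),
                     progress = FALSE)
    out$dir <- dir
    out$frames_dir <- frames_dir
  } else {
    out$frames <- frames
  }
  structure(out, class = "fw_session")
}
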