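# Reproducible end-to-end runs: detect -> measures -> bouts -> stats, with a
# machine-readable provenance record. Outputs are written atomically (tempfile
# + rename) so an interrupted run leaves no partial CSVs behind.

write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

default_run_config <- function() {
  list(
    delta = 25, connectivity = 8, min_area = 8, n_background = 9,
    interval_s = 120,
    min_on_frames = 27, min_off_frames = 10,
    span = 0.25, windows = feeding_windows(), unit = "per_fly",
    compare = "pretreatment"
  )
}

#' Run the full analysis pipeline on a session
#'
#' Executes detection, interval summarization, bout denoising and — when a
#' plate map with a two-level comparison factor is supplied — windowed
#' rank-sum statistics, writing every stage's CSV plus a provenance record
#' (`provenance.json`: config echo, seed if any, package version) sufficient
#' to reproduce the outputs exactly. Reruns on identical inputs produce
#' identical files.
#'
#' @param config Named list (or path to a JSON file) with paths `frames`
#'   (image-sequence directory), `layout` (layout JSON), optional `platemap`
#'   (CSV), `out_dir`, and any of the parameter fields of the default config:
#'   `delta`, `connectivity`, `min_area`, `n_background`, `interval_s`,
#'   `min_on_frames`, `min_off_frames`, `span`, `windows`, `unit`, `compare`.
#' @return Invisibly, a named list of output file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::fromJSON(config, simplifyDataFrame = FALSE)
  }
  cfg <- utils::modifyList(default_run_config(), config)
  for (p in c("frames", "layout")) {
    if (is.null(cfg[[p]])) abort(paste0("config is missing `", p, "`"))
  }
  if (!dir.exists(cfg$frames)) {
    abort(paste0("frames directory not found: ", cfg$frames))
  }
  if (!file.exists(cfg$layout)) {
    abort(paste0("layout file not found: ", cfg$layout))
  }
  if (!is.null(cfg$platemap) && !file.exists(cfg$platemap)) {
    abort(paste0("plate map not found: ", cfg$platemap))
  }
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  layout <- load_layout(cfg$layout)
  platemap <- if (!is.null(cfg$platemap)) read_platemap(cfg$platemap, layout)

  det <- detect_session(cfg$frames, layout, delta = cfg$delta,
                        connectivity = cfg$connectivity,
                        min_area = cfg$min_area,
                        n_background = cfg$n_background)
  intervals <- summarize_intervals(det, interval_s = cfg$interval_s)
  bp <- bout_params(fps = layout$fps, min_on_frames = cfg$min_on_frames,
                    min_off_frames = cfg$min_off_frames)
  bouts <- session_bouts(det, bp)

  paths <- list(
    detections = file.path(out_dir, "detections.csv"),
    intervals = file.path(out_dir, "intervals.csv"),
    bouts = file.path(out_dir, "bouts.csv")
  )
  write_atomic(function(p) write_detections(det, p), paths$detections)
  write_atomic(function(p) write_intervals(intervals, p), paths$intervals)
  write_atomic(function(p) readr::write_csv(as_tibble(bouts), p,
                                            progress = FALSE), paths$bouts)

  if (!is.null(platemap) && cfg$compare %in% names(platemap)) {
    lev <- sort(unique(platemap[[cfg$compare]]))
    if (length(lev) == 2) {
      windows <- lapply(cfg$windows, as.numeric)
      tests <- session_window_tests(det, platemap, cfg$compare, lev,
                                    windows, cfg$unit)
      paths$window_tests <- file.path(out_dir, "window_tests.csv")
      write_atomic(function(p) write_window_tests(tests, p),
                   paths$window_tests)
    }
  }

  prov <- list(
    tool = "flywell",
    version = as.character(utils::packageVersion("flywell")),
    config = cfg[!vapply(cfg, is.function, logical(1))]
  )
  paths$provenance <- file.path(out_dir, "provenance.json")
  write_atomic(function(p) {
    writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), p)
  }, paths$provenance)
  invisible(paths)
}

# Per-frame measures of a detections table shaped for windowed_tests, for the
# wells of one group.
group_series <- function(det, fps, wells, measure) {
  d <- as_tibble(det) |>
    filter(.data$well %in% wells) |>
    arrange(.data$well, .data$frame)
  if (measure == "food_fraction") {
    v <- as.numeric(d$food_flag)
  } else {
    d <- d |>
      group_by(.data$well) |>
      mutate(.v = distance_stream(.data$cx, .data$cy)) |>
      ungroup()
    v <- d$.v
  }
  tibble(fly = d$well, time_min = d$frame / (fps * 60), value = v)
}

session_window_tests <- function(det, platemap, compare, levels, windows,
                                 unit) {
  fps <- attr(det, "fps")
  bind_rows(lapply(c("food_fraction", "distance"), function(m) {
    a <- group_series(det, fps, platemap$well[platemap[[compare]] == levels[1]], m)
    b <- group_series(det, fps, platemap$well[platemap[[compare]] == levels[2]], m)
    windowed_tests(a, b, windows = windows, unit = unit,
                   measure = paste0(m, ": ", levels[1], " vs ", levels[2]))
  }))
}

#' Simulate a synthetic session to disk
#'
#' Thin wrapper over [generate_session()] that writes a complete session
#' directory consumable by [run_pipeline()], plus a provenance record. A seed
#' is mandatory: there is no implicit randomness.
#'
#' @param config Named list (or JSON path) with `dir`, `seed`, and any
#'   [sim_params()] field.
#' @return Invisibly, the session directory.
#' @export
run_simulate <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::fromJSON(config, simplifyDataFrame = FALSE)
  }
  if (is.null(config$seed)) abort("config is missing `seed`")
  if (is.null(config$dir)) abort("config is missing `dir`")
  seed <- config$seed
  dir <- config$dir
  par_names <- names(formals(sim_params))
  params <- do.call(sim_params, config[intersect(names(config), par_names)])
  session <- generate_session(params, seed = seed, dir = dir)
  prov <- list(tool = "flywell",
               version = as.character(utils::packageVersion("flywell")),
               seed = seed, params = unclass(params))
  writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "provenance.json"))
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
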