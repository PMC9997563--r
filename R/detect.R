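# Per-frame, per-well fly silhouette detection.
#
# Frames are numeric matrices of grayscale intensities in [0, 255], indexed
# [row, col] = [y + 1, x + 1] for 0-based pixel coordinates (x, y).

#' Read an image frame as a grayscale intensity matrix
#'
#' Reads a PNG or TIFF frame and converts it to grayscale intensities in
#' \[0, 255\] (Rec. 709 luminance for color images).
#'
#' @param path Image file path (`.png`, `.tif`/`.tiff`).
#' @return Numeric matrix `[height, width]` of intensities in \[0, 255\].
#' @export
read_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(paste0("unsupported frame format: .", ext))
  )
  if (length(dim(img)) == 3) {
    img <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
  }
  img * 255
}

#' List the frame files of an image-sequence directory
#'
#' Frames are ordered lexicographically by file name, the ordering contract
#' for image-sequence sessions.
#'
#' @param dir Directory containing PNG/TIFF frames.
#' @return Character vector of file paths in frame order.
#' @export
list_frames <- function(dir) {
  if (!dir.exists(dir)) abort(paste0("frame directory not found: ", dir))
  f <- list.files(dir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                  full.names = TRUE)
  f[order(basename(f), method = "radix")]
}

# Integer bounding box (1-based matrix indices) of a polygon, clipped to the
# frame.
well_bbox <- function(poly, frame_width, frame_height) {
  x0 <- max(0L, floor(min(poly[, 1])))
  x1 <- min(frame_width - 1L, ceiling(max(poly[, 1])))
  y0 <- max(0L, floor(min(poly[, 2])))
  y1 <- min(frame_height - 1L, ceiling(max(poly[, 2])))
  list(x0 = as.integer(x0), x1 = as.integer(x1),
       y0 = as.integer(y0), y1 = as.integer(y1))
}

crop_bbox <- function(frame, bbox) {
  frame[(bbox$y0 + 1L):(bbox$y1 + 1L), (bbox$x0 + 1L):(bbox$x1 + 1L),
        drop = FALSE]
}

# Logical matrix marking bbox pixels whose centers fall inside the polygon.
polygon_pixel_mask <- function(poly, bbox) {
  xs <- bbox$x0:bbox$x1
  ys <- bbox$y0:bbox$y1
  px <- rep(xs, each = length(ys))
  py <- rep(ys, times = length(xs))
  matrix(points_in_polygon(px, py, poly), nrow = length(ys))
}

#' Estimate a per-well background intensity map
#'
#' Computes the per-pixel temporal median over sampled frames within the
#' well's bounding box. With the fly occupying any given pixel in fewer than
#' half the sampled frames, the median recovers the unoccluded backlight
#' intensity, which makes it robust to static shading differences between
#' wells and cameras.
#'
#' A fly that camps on one spot (typically the food) for more than half the
#' sampled frames defeats the median there; for dark flies on a uniform
#' backlight the per-pixel temporal *maximum* (`probs = 1`) recovers the
#' unoccluded intensity whenever the fly leaves the spot at least once, and
#' is the default used by [detect_session()]. Use intermediate quantiles for
#' noisy sensors.
#'
#' @param frames List of frame matrices (at least 3), e.g. frames sampled
#'   evenly across the session.
#' @param well 4x2 corner matrix of the well polygon.
#' @param frame_width,frame_height Frame dimensions in pixels.
#' @param probs Temporal quantile used as the background (default 0.5, the
#'   per-pixel median; 1 gives the per-pixel maximum).
#' @return List with `bg` (background intensity matrix over the bounding
#'   box) and `bbox` (the bounding box, 0-based pixel ranges).
#' @export
estimate_background <- function(frames, well, frame_width, frame_height,
                                probs = 0.5) {
  if (length(frames) < 3) {
    abort("background estimation needs at least 3 sampled frames")
  }
  bbox <- well_bbox(well, frame_width, frame_height)
  crops <- lapply(frames, crop_bbox, bbox = bbox)
  bg <- if (probs == 1) {
    Reduce(pmax, crops)
  } else {
    stack <- array(unlist(crops), dim = c(dim(crops[[1]]), length(crops)))
    apply(stack, c(1, 2), stats::quantile, probs = probs, names = FALSE)
  }
  list(bg = bg, bbox = bbox)
}

#' Binarize a well region against its background
#'
#' A pixel is foreground (fly) iff its center lies inside the well polygon
#' and its intensity is strictly below `background - delta`: flies are dark
#' silhouettes on the near-infrared backlight.
#'
#' @param frame Frame matrix (full frame).
#' @param well 4x2 corner matrix of the well polygon.
#' @param background Result of [estimate_background()] for this well.
#' @param delta Intensity offset below background required to call a pixel
#'   foreground (0-255 scale); default 25.
#' @return List of class `fw_mask`: `mask` (logical matrix over the bounding
#'   box), `x0`, `y0` (0-based offsets of the bounding box in the frame).
#' @export
binarize_well <- function(frame, well, background, delta = 25) {
  if (delta < 0) abort("delta must be >= 0")
  bbox <- background$bbox
  crop <- crop_bbox(frame, bbox)
  inside <- polygon_pixel_mask(well, bbox)
  mask <- inside & (crop < background$bg - delta)
  structure(list(mask = mask, x0 = bbox$x0, y0 = bbox$y0), class = "fw_mask")
}

#' Label connected components of a binary mask
#'
#' Partitions the foreground into connected components under 4- or
#' 8-connectivity by building the pixel-adjacency graph and extracting its
#' connected components.
#'
#' @param mask An `fw_mask` from [binarize_well()], or a plain logical matrix
#'   (offsets then default to 0).
#' @param connectivity 4 (edge-adjacent) or 8 (edge- or corner-adjacent,
#'   default: thin silhouettes fragment under 4-connectivity).
#' @return Tibble with one row per component: `area` (pixel count), `cx`,
#'   `cy` (centroid, arithmetic mean of 0-based pixel positions), and
#'   `pixels` (list-column of n x 2 matrices of 0-based x, y positions,
#'   row-major pixel order).
#' @export
label_components <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) abort("connectivity must be 4 or 8")
  if (is.matrix(mask)) mask <- list(mask = mask, x0 = 0L, y0 = 0L)
  m <- mask$mask
  nr <- nrow(m)
  idx <- which(m)
  if (length(idx) == 0) {
    return(tibble(component = integer(), area = integer(),
                  cx = numeric(), cy = numeric(), pixels = list()))
  }
  pos <- integer(length(m))
  pos[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  edge_to <- function(off, keep) {
    nb <- idx + off
    ok <- keep & nb >= 1L & nb <= length(m)
    ok[ok] <- m[nb[ok]]
    cbind(pos[idx[ok]], pos[nb[ok]])
  }
  edges <- rbind(
    edge_to(1L, r < nr),        # down
    edge_to(nr, rep(TRUE, length(idx)))  # right
  )
  if (connectivity == 8) {
    edges <- rbind(edges,
                   edge_to(nr + 1L, r < nr),  # down-right
                   edge_to(nr - 1L, r > 1L))  # up-right
  }
  g <- igraph::make_graph(edges = as.vector(t(edges)), n = length(idx),
                          directed = FALSE)
  membership <- igraph::components(g)$membership
  x <- ((idx - 1L) %/% nr) + mask$x0   # 0-based x
  y <- (r - 1L) + mask$y0              # 0-based y
  comp_ids <- sort(unique(membership))
  comps <- lapply(comp_ids, function(k) {
    sel <- membership == k
    # row-major pixel order (by y, then x) for the documented tie-break
    ord <- order(y[sel], x[sel])
    cbind(x = x[sel][ord], y = y[sel][ord])
  })
  out <- tibble(
    component = seq_along(comps),
    area = vapply(comps, nrow, integer(1)),
    cx = vapply(comps, function(p) mean(p[, 1]), numeric(1)),
    cy = vapply(comps, function(p) mean(p[, 2]), numeric(1)),
    pixels = comps
  )
  # stable order: by first pixel in row-major order
  first_y <- vapply(comps, function(p) p[1, 2], numeric(1))
  first_x <- vapply(comps, function(p) p[1, 1], numeric(1))
  out <- out[order(first_y, first_x), ]
  out$component <- seq_len(nrow(out))
  out
}

#' Select the fly silhouette among labeled components
#'
#' Size filter: retains the largest component provided its area reaches
#' `min_area`; otherwise the fly is declared not found for the frame. On an
#' area tie the component whose top-left-most pixel comes first in row-major
#' order wins.
#'
#' @param components Tibble from [label_components()].
#' @param min_area Minimum silhouette area in pixels (default 8, rejecting
#'   dust specks while keeping a distant or partly occluded fly).
#' @return One-row tibble (the selected component) or `NULL` when no
#'   component passes the filter.
#' @export
select_fly <- function(components, min_area = 8) {
  if (nrow(components) == 0) return(NULL)
  best <- components[components$area == max(components$area), ]
  best <- best[1, ]  # components are stored in row-major first-pixel order
  if (best$area < min_area) return(NULL)
  best
}

#' Detect fly silhouettes across a session
#'
#' Runs the full per-frame, per-well detection chain — temporal-median
#' background, binarization, connected components, size filter — and computes
#' the per-frame food-interaction flag against each well's food circle.
#'
#' @param frames Either a directory of image frames (PNG/TIFF, lexicographic
#'   order) or a list of frame matrices.
#' @param layout An `fw_layout`.
#' @param delta Binarization offset, see [binarize_well()].
#' @param connectivity Component connectivity, see [label_components()].
#' @param min_area Size-filter threshold, see [select_fly()].
#' @param n_background Number of frames sampled evenly across the session for
#'   background estimation (default 9).
#' @param bg_probs Temporal quantile for the background (default 1, the
#'   per-pixel maximum; see [estimate_background()]).
#' @param fill_occluded When `TRUE` (default), background pixels more than
#'   `delta` below the well's median background level — pixels never observed
#'   unoccluded, e.g. under a fly camping at the food in every sampled frame —
#'   are inpainted with that median. Assumes a uniform backlight within the
#'   well; disable for wells with static dark features.
#' @param wells Optional subset of well ids to process.
#' @return Tibble of class `fw_detections` with columns `frame` (0-based),
#'   `well`, `found`, `cx`, `cy`, `area`, `food_flag`; attribute `fps` from
#'   the layout.
#' @export
detect_session <- function(frames, layout, delta = 25, connectivity = 8,
                           min_area = 8, n_background = 9, bg_probs = 1,
                           fill_occluded = TRUE, wells = NULL) {
  stopifnot(inherits(layout, "fw_layout"))
  from_dir <- is.character(frames) && length(frames) == 1
  paths <- NULL
  if (from_dir) {
    paths <- list_frames(frames)
    n_frames <- length(paths)
    get_frame <- function(i) read_frame(paths[i])
  } else {
    n_frames <- length(frames)
    get_frame <- function(i) frames[[i]]
  }
  if (n_frames == 0) abort("no frames to process")
  ids <- layout$wells$well
  if (!is.null(wells)) {
    unknown <- setdiff(wells, ids)
    if (length(unknown) > 0) {
      abort(paste0("unknown wells: ", paste(unknown, collapse = ", ")))
    }
    ids <- ids[ids %in% wells]
  }
  polys <- layout$wells$corners[match(ids, layout$wells$well)]
  food <- layout$food[match(ids, layout$food$well), ]

  # per-well background from frames sampled evenly across the session
  samp <- unique(round(seq(1, n_frames, length.out = max(3, min(n_background,
                                                                n_frames)))))
  if (length(samp) < 3) samp <- rep(samp, length.out = 3)
  bg_frames <- lapply(samp, get_frame)
  backgrounds <- lapply(polys, estimate_background, frames = bg_frames,
                        frame_width = layout$frame_width,
                        frame_height = layout$frame_height, probs = bg_probs)
  if (fill_occluded) {
    backgrounds <- lapply(backgrounds, function(b) {
      med <- median(b$bg)
      occluded <- b$bg < med - delta
      b$bg[occluded] <- med
      b
    })
  }
  inside_masks <- purrr::map2(polys, backgrounds,
                              function(p, b) polygon_pixel_mask(p, b$bbox))

  nw <- length(ids)
  found <- logical(n_frames * nw)
  cx <- rep(NA_real_, n_frames * nw)
  cy <- rep(NA_real_, n_frames * nw)
  area <- rep(NA_integer_, n_frames * nw)
  flag <- integer(n_frames * nw)
  for (fi in seq_len(n_frames)) {
    fr <- get_frame(fi)
    for (wi in seq_len(nw)) {
      b <- backgrounds[[wi]]
      crop <- crop_bbox(fr, b$bbox)
      mask <- inside_masks[[wi]] & (crop < b$bg - delta)
      comps <- label_components(
        structure(list(mask = mask, x0 = b$bbox$x0, y0 = b$bbox$y0),
                  class = "fw_mask"),
        connectivity = connectivity
      )
      sel <- select_fly(comps, min_area = min_area)
      k <- (fi - 1L) * nw + wi
      if (!is.null(sel)) {
        found[k] <- TRUE
        cx[k] <- sel$cx
        cy[k] <- sel$cy
        area[k] <- sel$area
        flag[k] <- food_interaction_flag(sel$pixels[[1]], food[wi, ])
      }
    }
  }
  out <- tibble(
    frame = rep(0:(n_frames - 1L), each = nw),
    well = rep(ids, times = n_frames),
    found = found, cx = cx, cy = cy, area = area, food_flag = flag
  )
  attr(out, "fps") <- layout$fps
  class(out) <- c("fw_detections", class(out))
  out
}

#' Write a detections table to CSV
#'
#' Columns `frame,well,found,cx,cy,area,food_flag`.
#'
#' @param detections An `fw_detections` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  readr::write_csv(as_tibble(detections), path, progress = FALSE)
  invisible(path)
}
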