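# Arena geometry: well polygons, food circles, frame metadata, plate map.
#
# Coordinate convention: 0-based pixel centers, origin at the top-left of the
# frame, x increasing rightward, y increasing downward. With y pointing down,
# a visually clockwise 4-corner polygon has positive shoelace sum.

#' The 96 standard plate well identifiers
#'
#' Row letters A-H crossed with column numbers 1-12, in row-major order
#' (A1, A2, ..., H12).
#'
#' @return Character vector of length 96.
#' @export
plate_wells <- function() {
  as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
}

#' Construct an arena layout
#'
#' An arena layout holds, for every well of the plate, the 4-corner polygon
#' bounding the well in image coordinates and the circle covering the feeding
#' port, together with the frame geometry and acquisition frame rate. The two
#' annotation tables are the persistent equivalent of marking well corners and
#' food-circle center/radius on a reference frame.
#'
#' @param wells Tibble with columns `well` (plate coordinate) and `corners`
#'   (list-column of 4x2 numeric matrices, columns x and y, stored clockwise
#'   in image coordinates).
#' @param food Tibble with columns `well`, `cx`, `cy`, `r` (center and radius
#'   of the food circle, pixels).
#' @param frame_width,frame_height Frame dimensions in pixels.
#' @param fps Acquisition frame rate (frames per second), default 30.
#' @param n_wells Expected number of wells; default covers the full 96-well
#'   plate. Synthetic sessions may use fewer.
#'
#' @return An object of class `fw_layout`.
#' @seealso [validate_layout()], [load_layout()], [save_layout()]
#' @export
arena_layout <- function(wells, food, frame_width, frame_height, fps = 30,
                         n_wells = 96L) {
  wells <- as_tibble(wells)
  food <- as_tibble(food)
  stopifnot(
    all(c("well", "corners") %in% names(wells)),
    all(c("well", "cx", "cy", "r") %in% names(food))
  )
  expected <- plate_wells()[seq_len(n_wells)]
  check_well_set(wells$well, expected, "wells")
  check_well_set(food$well, expected, "food")
  bad <- wells$well[!vapply(wells$corners, function(m) {
    is.numeric(m) && is.matrix(m) && nrow(m) == 4L && ncol(m) == 2L &&
      all(is.finite(m))
  }, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("well polygon must be a finite 4x2 matrix: ",
                 paste(bad, collapse = ", ")), class = "fw_schema_error")
  }
  bad_f <- food$well[!(is.finite(food$cx) & is.finite(food$cy) &
                         is.finite(food$r))]
  if (length(bad_f) > 0) {
    abort(paste0("food circle fields must be finite: ",
                 paste(bad_f, collapse = ", ")), class = "fw_schema_error")
  }
  if (!isTRUE(fps > 0)) abort("fps must be > 0", class = "fw_schema_error")
  structure(
    list(
      wells = wells[order_wells(wells$well), ],
      food = food[order_wells(food$well), ],
      frame_width = as.numeric(frame_width),
      frame_height = as.numeric(frame_height),
      fps = as.numeric(fps),
      n_wells = as.integer(n_wells)
    ),
    class = "fw_layout"
  )
}

order_wells <- function(ids) {
  row <- match(substr(ids, 1, 1), LETTERS)
  col <- as.integer(substring(ids, 2))
  order(row, col)
}

check_well_set <- function(ids, expected, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicate well ids in ", what, ": ",
                 paste(dup, collapse = ", ")), class = "fw_schema_error")
  }
  missing <- setdiff(expected, ids)
  extra <- setdiff(ids, expected)
  if (length(missing) > 0 || length(extra) > 0) {
    abort(paste0(
      what, " well set mismatch",
      if (length(missing) > 0) paste0("; missing: ", paste(missing, collapse = ", ")),
      if (length(extra) > 0) paste0("; unexpected: ", paste(extra, collapse = ", "))
    ), class = "fw_schema_error")
  }
  invisible(TRUE)
}

#' @export
print.fw_layout <- function(x, ...) {
  cat(sprintf("<fw_layout> %d wells, frame %gx%g px, %g fps\n",
              nrow(x$wells), x$frame_width, x$frame_height, x$fps))
  invisible(x)
}

# Signed shoelace sum; positive for visually clockwise polygons when y points
# down (image convention).
polygon_signed_area <- function(m) {
  x <- m[, 1]; y <- m[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Save an arena layout to a JSON schema file
#'
#' Writes the layout as a versioned JSON document. Coordinates are written at
#' full double precision so that a save/load round trip is exact.
#'
#' @param layout An `fw_layout`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_layout <- function(layout, path) {
  stopifnot(inherits(layout, "fw_layout"))
  doc <- list(
    schema = "flywell-arena-layout",
    version = 1L,
    frame = list(width = layout$frame_width, height = layout$frame_height,
                 fps = layout$fps),
    n_wells = layout$n_wells,
    wells = lapply(seq_len(nrow(layout$wells)), function(i) {
      list(well = layout$wells$well[i],
           corners = unname(layout$wells$corners[[i]]))
    }),
    food = lapply(seq_len(nrow(layout$food)), function(i) {
      list(well = layout$food$well[i], cx = layout$food$cx[i],
           cy = layout$food$cy[i], r = layout$food$r[i])
    })
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Load an arena layout from a JSON schema file
#'
#' @param path Path to a layout file written by [save_layout()] (schema
#'   `flywell-arena-layout`, version 1).
#' @return An `fw_layout`.
#' @export
load_layout <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("layout file not found: ", path), class = "fw_schema_error")
  }
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  if (!identical(doc$schema, "flywell-arena-layout")) {
    abort("not a flywell arena layout file", class = "fw_schema_error")
  }
  wells <- tibble(
    well = vapply(doc$wells, `[[`, character(1), "well"),
    corners = lapply(doc$wells, function(w) {
      m <- do.call(rbind, lapply(w$corners, unlist))
      storage.mode(m) <- "double"
      colnames(m) <- c("x", "y")
      m
    })
  )
  food <- tibble(
    well = vapply(doc$food, `[[`, character(1), "well"),
    cx = vapply(doc$food, function(f) as.numeric(f$cx), numeric(1)),
    cy = vapply(doc$food, function(f) as.numeric(f$cy), numeric(1)),
    r = vapply(doc$food, function(f) as.numeric(f$r), numeric(1))
  )
  bad_r <- food$well[!(is.finite(food$r) & food$r > 0)]
  if (length(bad_r) > 0) {
    abort(paste0("food circle radius must be > 0: ",
                 paste(bad_r, collapse = ", ")), class = "fw_schema_error")
  }
  n_wells <- if (!is.null(doc$n_wells)) as.integer(doc$n_wells) else 96L
  arena_layout(wells, food, doc$frame$width, doc$frame$height,
               fps = doc$frame$fps, n_wells = n_wells)
}

# Point-in-polygon with an explicit on-edge rule: points exactly on an edge
# (within `eps`) count as inside. Even-odd crossing test, vectorized over
# points for one polygon.
points_in_polygon <- function(px, py, poly, eps = 1e-9) {
  n <- length(px)
  inside <- logical(n)
  on_edge <- logical(n)
  nv <- nrow(poly)
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # on-segment: zero cross product and within the segment's bounding box
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    seg_len2 <- (xj - xi)^2 + (yj - yi)^2
    tol <- eps * max(1, sqrt(seg_len2))
    on_this <- abs(cross) <= tol &
      px >= pmin(xi, xj) - eps & px <= pmax(xi, xj) + eps &
      py >= pmin(yi, yj) - eps & py <= pmax(yi, yj) + eps
    on_edge <- on_edge | on_this
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Map image points to wells
#'
#' Returns, for each point, the id of the well whose polygon contains it, or
#' `NA` if the point lies outside every well. A point exactly on a polygon
#' edge belongs to that well; if two wells' edges coincide at the point, the
#' lexicographically smaller well id wins (deterministic tie-break).
#'
#' @param points Data frame with columns `x` and `y` (image pixels), or a
#'   length-2 numeric vector `c(x, y)` for a single point.
#' @param layout An `fw_layout`.
#' @return Character vector of well ids (`NA` where no well contains the
#'   point).
#' @export
well_of_point <- function(points, layout) {
  stopifnot(inherits(layout, "fw_layout"))
  if (is.numeric(points) && is.null(dim(points))) {
    points <- tibble(x = points[1], y = points[2])
  }
  px <- points$x
  py <- points$y
  hits <- matrix(FALSE, nrow = length(px), ncol = nrow(layout$wells))
  for (k in seq_len(nrow(layout$wells))) {
    hits[, k] <- points_in_polygon(px, py, layout$wells$corners[[k]])
  }
  ids <- layout$wells$well
  # lexicographic (C-locale) tie-break among containing wells
  ord <- order(method = "radix", ids)
  apply(hits[, ord, drop = FALSE], 1, function(h) {
    w <- which(h)
    if (length(w) == 0) NA_character_ else ids[ord][w[1]]
  })
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

polygons_overlap <- function(a, b) {
  # centroid containment or proper edge crossing; polygons that merely touch
  # along a shared wall do not trigger either test
  ca <- colMeans(a); cb <- colMeans(b)
  if (points_in_polygon(ca[1], ca[2], b) || points_in_polygon(cb[1], cb[2], a)) {
    return(TRUE)
  }
  for (i in seq_len(4)) {
    for (j in seq_len(4)) {
      if (segments_intersect(a[i, ], a[i %% 4 + 1, ], b[j, ], b[j %% 4 + 1, ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Validate an arena layout
#'
#' Checks every layout invariant and returns the violations as a tibble
#' rather than raising. Hard violations (severity `"error"`) break the layout
#' contract; `"warning"` rows flag suspicious but tolerated geometry, e.g. a
#' food circle that is not fully inside its well (annotation jitter around
#' the feeding port is expected) or well polygons that touch/overlap at
#' shared walls.
#'
#' @param layout An `fw_layout`.
#' @return Tibble with columns `well`, `rule`, `severity`, `message`; zero
#'   rows when every invariant holds.
#' @export
validate_layout <- function(layout) {
  stopifnot(inherits(layout, "fw_layout"))
  v <- list()
  add <- function(well, rule, severity, message) {
    v[[length(v) + 1]] <<- tibble(well = well, rule = rule,
                                  severity = severity, message = message)
  }
  for (i in seq_len(nrow(layout$wells))) {
    id <- layout$wells$well[i]
    m <- layout$wells$corners[[i]]
    a <- polygon_signed_area(m)
    if (abs(a) <= 0) {
      add(id, "polygon_area", "error", "polygon area must be > 0")
    } else if (a < 0) {
      add(id, "polygon_orientation", "error",
          "corners must be stored clockwise (image coordinates)")
    }
    if (any(m[, 1] < 0 | m[, 1] > layout$frame_width - 1 |
              m[, 2] < 0 | m[, 2] > layout$frame_height - 1)) {
      add(id, "corners_in_frame", "error", "corner outside frame bounds")
    }
  }
  for (i in seq_len(nrow(layout$food))) {
    id <- layout$food$well[i]
    f <- layout$food[i, ]
    if (!isTRUE(f$r > 0)) {
      add(id, "food_radius", "error", "food circle radius must be > 0")
      next
    }
    k <- match(id, layout$wells$well)
    poly <- layout$wells$corners[[k]]
    if (!points_in_polygon(f$cx, f$cy, poly)) {
      add(id, "food_center_in_well", "error",
          "food circle center outside its well polygon")
    } else {
      # circle extent fully inside the well is expected but not required
      probe_x <- f$cx + c(f$r, -f$r, 0, 0)
      probe_y <- f$cy + c(0, 0, f$r, -f$r)
      if (!all(points_in_polygon(probe_x, probe_y, poly))) {
        add(id, "food_circle_in_well", "warning",
            "food circle extends beyond its well polygon")
      }
    }
  }
  n <- nrow(layout$wells)
  for (i in seq_len(max(0, n - 1))) {
    for (j in seq(i + 1, n)) {
      if (polygons_overlap(layout$wells$corners[[i]],
                           layout$wells$corners[[j]])) {
        pair <- paste(layout$wells$well[i], layout$wells$well[j], sep = "+")
        add(pair, "polygon_overlap", "warning",
            "well polygons overlap or share area")
      }
    }
  }
  if (length(v) == 0) {
    tibble(well = character(), rule = character(), severity = character(),
           message = character())
  } else {
    bind_rows(v)
  }
}

#' Read a plate map CSV
#'
#' The plate map assigns experimental factors to wells. Expected header:
#' `well,sex,pretreatment,diet_kcal,flies_per_well,alive`.
#'
#' @param path CSV file path.
#' @param layout Optional `fw_layout`; when given, every mapped well must
#'   exist in the layout.
#' @return Tibble with one row per mapped well.
#' @export
read_platemap <- function(path, layout = NULL) {
  pm <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("well", "sex", "pretreatment", "diet_kcal", "flies_per_well",
                "alive")
  missing <- setdiff(required, names(pm))
  if (length(missing) > 0) {
    abort(paste0("plate map missing columns: ", paste(missing, collapse = ", ")),
          class = "fw_schema_error")
  }
  bad_sex <- setdiff(unique(pm$sex), c("female", "male"))
  if (length(bad_sex) > 0) {
    abort(paste0("sex must be female/male, got: ", paste(bad_sex, collapse = ", ")),
          class = "fw_schema_error")
  }
  bad_pre <- setdiff(unique(pm$pretreatment), c("fed", "starved"))
  if (length(bad_pre) > 0) {
    abort(paste0("pretreatment must be fed/starved, got: ",
                 paste(bad_pre, collapse = ", ")), class = "fw_schema_error")
  }
  if (any(pm$flies_per_well < 1 | pm$flies_per_well > 3)) {
    abort("flies_per_well must be in [1, 3]", class = "fw_schema_error")
  }
  pm$alive <- as.logical(pm$alive)
  if (!is.null(layout)) {
    unknown <- setdiff(pm$well, layout$wells$well)
    if (length(unknown) > 0) {
      abort(paste0("plate map wells not in layout: ",
                   paste(unknown, collapse = ", ")), class = "fw_schema_error")
    }
  }
  pm
}

#' Write a plate map CSV
#'
#' @param platemap Tibble as returned by [read_platemap()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_platemap <- function(platemap, path) {
  readr::write_csv(platemap, path, progress = FALSE)
  invisible(path)
}
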