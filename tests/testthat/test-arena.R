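# Arena geometry: layout schema I/O, point-to-well mapping, validation.

full_layout <- synthetic_layout(sim_params(n_wells = 96, well_px = 40,
                                           fly_axes = c(5, 3),
                                           food_radius = 10))

test_that("layout save/load round trip is exact", {
  path <- withr::local_tempfile(fileext = ".json")
  save_layout(full_layout, path)
  back <- load_layout(path)
  expect_identical(back$wells$well, full_layout$wells$well)
  for (i in seq_len(96)) {
    expect_equal(back$wells$corners[[i]], full_layout$wells$corners[[i]],
                 tolerance = 0)
  }
  expect_equal(back$food, full_layout$food, tolerance = 0)
  expect_identical(back$fps, full_layout$fps)
})

test_that("layout schema errors name the offending well", {
  path <- withr::local_tempfile(fileext = ".json")
  doc <- jsonlite::fromJSON(save_layout(full_layout, path) |> readLines() |>
                              paste(collapse = "\n"),
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  # drop well H12
  drop <- vapply(doc$wells, function(w) w$well == "H12", logical(1))
  doc$wells <- doc$wells[!drop]
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), path)
  expect_error(load_layout(path), "H12")

  # zero radius in one well
  doc <- jsonlite::fromJSON(save_layout(full_layout, path) |> readLines() |>
                              paste(collapse = "\n"),
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  k <- which(vapply(doc$food, function(f) f$well == "C7", logical(1)))
  doc$food[[k]]$r <- 0
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), path)
  expect_error(load_layout(path), "C7")

  expect_error(load_layout(withr::local_tempfile()), "not found")
})

test_that("a generated session layout parses and validates cleanly", {
  path <- withr::local_tempfile(fileext = ".json")
  lay <- synthetic_layout(sim_params(n_wells = 8))
  save_layout(lay, path)
  back <- load_layout(path)
  v <- validate_layout(back)
  expect_identical(nrow(v[v$severity == "error", ]), 0L)
})

test_that("well_of_point maps interior points and rejects outside points", {
  c4 <- full_layout$wells$corners[[match("C4", full_layout$wells$well)]]
  centroid <- colMeans(c4)
  expect_identical(well_of_point(centroid, full_layout), "C4")
  expect_true(is.na(well_of_point(c(-50, -50), full_layout)))
})

test_that("well_of_point agrees with a winding-number oracle on 1,000 points", {
  set.seed(20260926)
  n <- 1000
  px <- runif(n, -5, full_layout$frame_width + 5)
  py <- runif(n, -5, full_layout$frame_height + 5)
  got <- well_of_point(tibble::tibble(x = px, y = py), full_layout)
  expected <- rep(NA_character_, n)
  ids <- full_layout$wells$well
  ord <- order(ids, method = "radix")
  for (k in ord) {
    hit <- oracle_point_in_polygon(px, py, full_layout$wells$corners[[k]])
    fill <- hit & is.na(expected)
    expected[fill] <- ids[k]
  }
  expect_identical(got, expected)
})

test_that("boundary points belong to a well; shared edges break ties lexicographically", {
  # two touching unit squares sharing the edge x = 10
  mk <- function(x0) {
    m <- rbind(c(x0, 0), c(x0 + 10, 0), c(x0 + 10, 10), c(x0, 10))
    colnames(m) <- c("x", "y"); m
  }
  lay <- arena_layout(
    wells = tibble::tibble(well = c("A1", "A2"),
                           corners = list(mk(0), mk(10))),
    food = tibble::tibble(well = c("A1", "A2"), cx = c(5, 15), cy = c(5, 5),
                          r = 2),
    frame_width = 30, frame_height = 20, fps = 30, n_wells = 2
  )
  expect_identical(well_of_point(c(10, 5), lay), "A1")  # shared edge -> A1
  expect_identical(well_of_point(c(0, 0), lay), "A1")   # corner
  expect_identical(well_of_point(c(12, 5), lay), "A2")
})

test_that("validate_layout reports violations without raising", {
  expect_identical(nrow(validate_layout(full_layout)), 0L)

  bad <- full_layout
  bad$food$r[bad$food$well == "B3"] <- 0
  v <- validate_layout(bad)
  expect_identical(v$well[v$rule == "food_radius"], "B3")
  expect_identical(v$severity[v$rule == "food_radius"], "error")

  # overlapping polygons are reported with both ids
  ovl <- full_layout
  ovl$wells$corners[[2]] <- full_layout$wells$corners[[1]] + 2
  ovl$food$cx[2] <- ovl$food$cx[1] + 2
  ovl$food$cy[2] <- ovl$food$cy[1] + 2
  v <- validate_layout(ovl)
  expect_true(any(grepl("A1", v$well[v$rule == "polygon_overlap"]) &
                    grepl("A2", v$well[v$rule == "polygon_overlap"])))
})

test_that("no point maps to two wells in a valid layout", {
  set.seed(42)
  px <- runif(300, 0, full_layout$frame_width)
  py <- runif(300, 0, full_layout$frame_height)
  counts <- rowSums(vapply(full_layout$wells$corners, function(poly) {
    flywell:::points_in_polygon(px, py, poly)
  }, logical(300)))
  expect_true(all(counts <= 1))
})

test_that("plate map reading enforces vocabulary and layout membership", {
  lay <- synthetic_layout(sim_params(n_wells = 4))
  pm <- tibble::tibble(well = c("A1", "A2", "A3", "A4"),
                       sex = c("female", "male", "female", "male"),
                       pretreatment = c("fed", "fed", "starved", "starved"),
                       diet_kcal = c(100, 100, 400, 400),
                       flies_per_well = 1L, alive = c(TRUE, TRUE, FALSE, TRUE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_platemap(pm, path)
  back <- read_platemap(path, lay)
  expect_equal(back$alive, pm$alive)

  pm_bad <- pm; pm_bad$sex[1] <- "unknown"
  write_platemap(pm_bad, path)
  expect_error(read_platemap(path, lay), "sex")

  pm_bad <- pm; pm_bad$well[1] <- "H12"
  write_platemap(pm_bad, path)
  expect_error(read_platemap(path, lay), "H12")
})
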