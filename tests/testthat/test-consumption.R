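# Standard curves and dye-based consumption quantification.

test_that("standard curve fitting recovers an exact line", {
  pts <- tibble::tibble(known_amount = c(0, 1, 2, 4),
                        signal = 2 * c(0, 1, 2, 4) + 1)
  cv <- suppressWarnings(fit_standard_curve(pts))
  expect_equal(cv$slope, 2)
  expect_equal(cv$intercept, 1)
  expect_equal(cv$r_squared, 1)

  expect_error(fit_standard_curve(pts[1, ]), "at least 2")
  expect_error(fit_standard_curve(tibble::tibble(known_amount = c(2, 2, 2),
                                                 signal = c(1, 2, 3))),
               "at least 2 distinct")
  expect_warning(
    fit_standard_curve(tibble::tibble(known_amount = c(0, 1, 2, 3),
                                      signal = c(0, 3, 1, 2))),
    "r\\^2"
  )
})

test_that("least-squares estimates match the normal-equations oracle", {
  set.seed(83)
  for (rep in 1:20) {
    x <- sort(runif(8, 0, 5))
    y <- 3.2 * x + 0.4 + rnorm(8, 0, 0.2)
    cv <- suppressWarnings(
      fit_standard_curve(tibble::tibble(known_amount = x, signal = y)))
    ab <- oracle_ols(x, y)
    expect_equal(cv$intercept, ab[1])
    expect_equal(cv$slope, ab[2])
  }
})

test_that("quantification inverts the curve and clamps negative amounts", {
  cv <- suppressWarnings(fit_standard_curve(
    tibble::tibble(known_amount = c(0, 1), signal = c(0, 1))))
  r <- tibble::tibble(well = "A1", signal = 0.5, flies_per_well = 1)
  expect_equal(quantify(r, cv)$amount_per_fly, 0.5)

  below <- tibble::tibble(well = "A2", signal = -0.2, flies_per_well = 1)
  expect_warning(out <- quantify(below, cv), "clamped")
  expect_equal(out$amount_per_fly, 0)

  flat <- cv; flat$slope <- 0
  expect_error(quantify(r, flat), "slope")
})

test_that("noiseless forward-inverse round trip is exact", {
  slope <- 0.8; intercept <- 0.05
  cv <- suppressWarnings(fit_standard_curve(tibble::tibble(
    known_amount = c(0, 0.05, 0.1, 0.2, 0.4),
    signal = slope * c(0, 0.05, 0.1, 0.2, 0.4) + intercept
  )))
  set.seed(89)
  true_amounts <- runif(96, 0.02, 0.3)
  plate <- tibble::tibble(well = plate_wells(),
                          signal = slope * true_amounts + intercept,
                          flies_per_well = 1)
  out <- quantify(plate, cv)
  expect_equal(out$amount_per_fly, true_amounts, tolerance = 1e-12)
})

test_that("noisy synthetic plates recover group means within 2% bias", {
  slope <- 1.6; intercept <- 0.1
  cv <- suppressWarnings(fit_standard_curve(tibble::tibble(
    known_amount = seq(0, 0.5, by = 0.05),
    signal = slope * seq(0, 0.5, by = 0.05) + intercept
  )))
  set.seed(97)
  true_amounts <- runif(96, 0.05, 0.25)
  noise <- rnorm(96, 0, 0.002)
  plate <- tibble::tibble(well = plate_wells(),
                          signal = slope * true_amounts + intercept + noise,
                          flies_per_well = 1)
  out <- quantify(plate, cv)
  bias <- abs(mean(out$amount_per_fly) - mean(true_amounts)) /
    mean(true_amounts)
  expect_lt(bias, 0.02)
})

test_that("per-hour rates follow the worked example", {
  expect_equal(per_hour_rate(0.10, 2), 0.05)
  expect_equal(per_hour_rate(0, 5), 0)
  expect_equal(per_hour_rate(0.7, 1), 0.7)
  expect_error(per_hour_rate(1, 0), "duration")
})

test_that("dead flies are excluded with a complete, disjoint report", {
  pm <- tibble::tibble(well = plate_wells(),
                       sex = "female", pretreatment = "fed", diet_kcal = 100,
                       flies_per_well = 1L,
                       alive = rep(TRUE, 96))
  pm$alive[c(5, 40, 77)] <- FALSE
  plate <- tibble::tibble(well = plate_wells(), signal = runif(96),
                          flies_per_well = 1)

  kept <- exclude_dead(plate, pm)
  rep_tbl <- excluded_wells(kept)
  expect_identical(nrow(kept), 93L)
  expect_identical(nrow(rep_tbl), 3L)
  expect_setequal(c(kept$well, rep_tbl$well), plate$well)
  expect_length(intersect(kept$well, rep_tbl$well), 0)

  all_alive <- pm; all_alive$alive <- TRUE
  kept2 <- exclude_dead(plate, all_alive)
  expect_identical(nrow(kept2), 96L)
  expect_identical(nrow(excluded_wells(kept2)), 0L)

  expect_error(exclude_dead(tibble::tibble(well = "Z9", signal = 1,
                                           flies_per_well = 1), pm),
               "Z9")
})

test_that("group means and SEMs reproduce a brute-force recomputation", {
  set.seed(103)
  pm <- tibble::tibble(well = plate_wells(), sex = rep(c("female", "male"), 48),
                       pretreatment = "fed", diet_kcal = 100,
                       flies_per_well = 1L, alive = runif(96) > 0.05)
  cv <- suppressWarnings(fit_standard_curve(
    tibble::tibble(known_amount = c(0, 1), signal = c(0, 2))))
  plate <- tibble::tibble(well = plate_wells(), signal = runif(96, 0.1, 1),
                          flies_per_well = 1)
  out <- quantify(exclude_dead(plate, pm), cv)
  got <- dplyr::summarise(
    dplyr::group_by(dplyr::left_join(out, pm, by = "well"), sex),
    mean = mean(amount_per_fly),
    sem = stats::sd(amount_per_fly) / sqrt(dplyr::n()), .groups = "drop")
  for (s in c("female", "male")) {
    keep <- pm$well[pm$sex == s & pm$alive]
    vals <- (plate$signal[match(keep, plate$well)] - 0) / 2
    expect_equal(got$mean[got$sex == s], mean(vals))
    expect_equal(got$sem[got$sex == s], stats::sd(vals) / sqrt(length(vals)))
  }
})

test_that("tidy and glance summarize a standard curve", {
  cv <- suppressWarnings(fit_standard_curve(tibble::tibble(
    known_amount = 0:5, signal = 0.7 * (0:5) + 0.2 + rnorm(6, 0, 0.01))))
  td <- tidy(cv)
  expect_identical(td$term, c("(Intercept)", "known_amount"))
  gl <- glance(cv)
  expect_equal(gl$slope, cv$slope)
  expect_gt(gl$r.squared, 0.99)
})
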