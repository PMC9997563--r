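# Run-length encoding and the feeding-bout noise-removal rule.

test_that("burst frame threshold follows fps x sips x sip duration", {
  expect_equal(burst_frame_threshold(7, 0.13, 30), 27.3)
  expect_equal(burst_frame_threshold(1, 1.0, 30), 30)
  expect_equal(burst_frame_threshold(0, 0.5, 30), 0)
  # downstream integer threshold is the floor
  expect_identical(bout_params()$min_on_frames, 27L)
  expect_identical(bout_params()$min_off_frames, 10L)
})

test_that("run-length encoding is the inverse of decoding", {
  r <- run_length_encode(c(1L, 1L, 0L))
  expect_equal(r$state, c(1L, 0L))
  expect_equal(r$start_frame, c(0L, 2L))
  expect_equal(r$length_frames, c(2L, 1L))

  expect_identical(nrow(run_length_encode(integer(0))), 0L)

  set.seed(11)
  for (rep in 1:50) {
    x <- random_flag_series(sample(1:200, 1), runif(1, 0.1, 0.9))
    runs <- run_length_encode(x)
    expect_identical(run_length_decode(runs), x)
    # runs alternate and cover the series
    if (nrow(runs) > 1) expect_true(all(diff(runs$state) != 0))
    expect_identical(sum(runs$length_frames), length(x))
  }
})

test_that("denoising reproduces the hand-simulated printed-parameter cases", {
  p <- bout_params()  # min_on 27, min_off 10
  expect_identical(denoise_flags(rep(0L, 50), p), rep(0L, 50))

  # 30 ones, 5 zeros, 30 ones: the 5-frame gap is closed -> 65 ones
  x <- c(rep(1L, 30), rep(0L, 5), rep(1L, 30))
  expect_identical(denoise_flags(x, p), rep(1L, 65))
  expect_identical(denoise_flags(x, p), oracle_denoise(x))

  # isolated 20-frame contact flanked by long absences: removed
  y <- c(rep(0L, 12), rep(1L, 20), rep(0L, 12))
  expect_identical(denoise_flags(y, p), rep(0L, 44))
  expect_identical(denoise_flags(y, p), oracle_denoise(y))
})

test_that("denoising matches the single-frame-flip reference on random series", {
  set.seed(23)
  for (rep in 1:60) {
    x <- random_flag_series(sample(30:150, 1), runif(1, 0.2, 0.8))
    expect_identical(denoise_flags(x), oracle_denoise(x))
  }
})

test_that("denoising is idempotent and satisfies the run-length constraints", {
  set.seed(31)
  p <- bout_params()
  for (rep in 1:200) {
    x <- random_flag_series(sample(10:300, 1), runif(1, 0.05, 0.95))
    once <- denoise_flags(x, p)
    expect_identical(denoise_flags(once, p), once)
    runs <- run_length_encode(once)
    n <- nrow(runs)
    if (n > 0) {
      on <- runs$length_frames[runs$state == 1L]
      expect_true(all(on >= p$min_on_frames))
      interior <- runs[runs$state == 0L &
                         seq_len(n) != 1L & seq_len(n) != n, ]
      expect_true(all(interior$length_frames >= p$min_off_frames))
    }
  }
})

test_that("leading and trailing zero runs are never flipped", {
  x <- c(rep(0L, 3), rep(1L, 40), rep(0L, 4))
  out <- denoise_flags(x)
  expect_identical(out[1:3], rep(0L, 3))
  expect_identical(out[44:47], rep(0L, 4))
  expect_identical(out[4:43], rep(1L, 40))
})

test_that("flagged time is monotone in the thresholds", {
  set.seed(47)
  for (rep in 1:40) {
    x <- random_flag_series(sample(50:200, 1), runif(1, 0.3, 0.7))
    base <- sum(denoise_flags(x, bout_params(min_on_frames = 27,
                                             min_off_frames = 10)))
    lower_on <- sum(denoise_flags(x, bout_params(min_on_frames = 13,
                                                 min_off_frames = 10)))
    higher_off <- sum(denoise_flags(x, bout_params(min_on_frames = 27,
                                                   min_off_frames = 20)))
    expect_gte(lower_on, base)
    expect_gte(higher_off, base)
  }
})

test_that("bout tables list the denoised feeding blocks in seconds", {
  p <- bout_params()
  x <- c(rep(0L, 30), rep(1L, 60), rep(0L, 30))
  bt <- bout_table(x, p)
  expect_identical(nrow(bt), 1L)
  expect_equal(bt$start_s, 1)
  expect_equal(bt$duration_s, 2)

  expect_identical(nrow(bout_table(rep(0L, 100), p)), 0L)

  set.seed(53)
  y <- random_flag_series(500, 0.6)
  den <- denoise_flags(y, p)
  expect_identical(nrow(bout_table(y, p)),
                   sum(run_length_encode(den)$state == 1L))
})

test_that("bouts recover the true states from noisy flags on synthetic sessions", {
  p <- sim_params(n_wells = 8, duration_s = 120)
  gt <- simulate_behavior(p, seed = 613, positions = FALSE)
  set.seed(614)
  acc <- vapply(split(gt$truth, gt$truth$well), function(tr) {
    truth <- as.integer(tr$state[order(tr$frame)] == "at_food")
    noisy <- ifelse(runif(length(truth)) < 0.05, 1L - truth, truth)
    mean(denoise_flags(noisy, bout_params()) == truth)
  }, numeric(1))
  expect_gte(mean(acc), 0.95)
})

test_that("burst-mode flags denoise back to the underlying feeding states", {
  p <- sim_params(n_wells = 4, duration_s = 120, burst_mode = TRUE)
  gt <- simulate_behavior(p, seed = 29, positions = FALSE)
  by_well <- split(gt$truth, gt$truth$well)
  agreement <- vapply(by_well, function(tr) {
    tr <- tr[order(tr$frame), ]
    truth <- as.integer(tr$state == "at_food")
    mean(denoise_flags(tr$flag_raw, bout_params()) == truth)
  }, numeric(1))
  expect_gte(mean(agreement), 0.95)
  # raw burst flags differ from the states (gaps between bursts)
  expect_true(any(gt$truth$flag_raw != as.integer(gt$truth$state == "at_food")))
})
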