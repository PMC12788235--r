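# Gap interpolation / exclusion and tap-based synchronization.

test_that("gaps of 5 frames are filled, 6 frames split the segment", {
  rec5 <- mark_missing(quiet_recording(1000), at = 400, len = 5)
  out5 <- interpolate_gaps(rec5, max_gap = 5)
  expect_equal(nrow(out5$segments), 1)
  expect_false(any(out5$missing))

  rec6 <- mark_missing(quiet_recording(1000), at = 400, len = 6)
  out6 <- interpolate_gaps(rec6, max_gap = 5)
  expect_equal(nrow(out6$segments), 2)
  expect_equal(unname(out6$segments[1, ]), c(1L, 400L))
  expect_equal(unname(out6$segments[2, ]), c(406L, 1001L))
})

test_that("clean recordings pass through unchanged", {
  rec <- quiet_recording(500)
  out <- interpolate_gaps(rec)
  expect_identical(out$imu, rec$imu)
  expect_identical(out$segments, rec$segments)
})

test_that("linear interpolation reproduces a linear ramp exactly", {
  n <- 300
  rec <- quiet_recording(n)
  ramp <- matrix(rep(seq_len(n) * 0.5, 6), n, 6)
  rec$imu <- ramp
  colnames(rec$imu) <- gaitxpop:::IMU_CHANNELS
  rec <- mark_missing(rec, at = 100, len = 3)
  out <- interpolate_gaps(rec)
  expect_equal(out$imu, ramp, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(out, "n_interpolated"), 3L)
})

test_that("valid samples are never altered by interpolation", {
  rec <- tiny_recording(seed = 8, duration = 20)
  gapped <- inject_gaps(rec, 0.3, seed = 1)
  out <- interpolate_gaps(gapped)
  keep <- !gapped$missing
  expect_identical(out$imu[keep, ], gapped$imu[keep, ])
})

test_that("edge gaps are excluded regardless of length", {
  rec <- mark_missing(quiet_recording(500), at = 1, len = 3)
  out <- interpolate_gaps(rec)
  expect_equal(nrow(out$segments), 1)
  expect_equal(unname(out$segments[1, "start"]), 4L)

  rec2 <- mark_missing(quiet_recording(500), at = 498, len = 3)
  out2 <- interpolate_gaps(rec2)
  expect_equal(unname(out2$segments[1, ]), c(1L, 498L))
})

test_that("fully missing recordings yield an empty segment list with a warning", {
  rec <- mark_missing(quiet_recording(300), at = 1, len = 300)
  expect_warning(out <- interpolate_gaps(rec), "no valid samples")
  expect_equal(nrow(out$segments), 0)
})

test_that("segment cover equals the valid samples after interpolation", {
  rec <- inject_gaps(tiny_recording(seed = 3, duration = 30), 0.5, seed = 9)
  out <- interpolate_gaps(rec)
  covered <- rep(FALSE, nrow(out$imu))
  for (s in seq_len(nrow(out$segments))) {
    covered[out$segments[s, "start"]:(out$segments[s, "end"] - 1L)] <- TRUE
  }
  expect_identical(covered, !out$missing)
})

test_that("detect_taps refuses pure noise and finds planted taps", {
  rec <- quiet_recording(1500)
  rec$imu[, 1:3] <- rec$imu[, 1:3] + matrix(rnorm(1500 * 3, 0, 0.05), 1500)
  expect_error(detect_taps(rec), "tap not found")
  tapped <- add_sync_taps(rec, amplitude = 40, at = c(150, 1350))
  found <- detect_taps(tapped)
  expect_length(found, 2)
  expect_false(is.unsorted(found))
  expect_true(all(abs(found - c(150, 1350)) <= 1))
})

test_that("synchronize recovers a constructed shift with unit scale", {
  rec <- quiet_recording(2000)
  rec$imu[, 1:3] <- rec$imu[, 1:3] + matrix(rnorm(2000 * 3, 0, 0.02), 2000)
  a <- add_sync_taps(rec, amplitude = 40, at = c(100, 1900))
  # b = a delayed by 37 samples
  b <- a
  b$imu <- rbind(matrix(rep(a$imu[1, ], each = 37), 37, 6), a$imu)
  b$angles <- rbind(matrix(rep(a$angles[1, ], each = 37), 37, 6), a$angles)
  b$missing <- c(rep(FALSE, 37), a$missing)
  b$segments <- cbind(start = 1L, end = nrow(b$imu) + 1L)
  res <- synchronize(a, b)
  expect_equal(res$sync$offset, 37)
  expect_equal(res$sync$scale, 1.0, tolerance = 1e-6)

  ident <- synchronize(a, a)
  expect_equal(ident$sync$offset, 0)
  expect_equal(ident$sync$scale, 1.0)
})

test_that("synchronize estimates a constructed 0.1% clock drift", {
  n <- 20000
  rec <- quiet_recording(n)
  rec$imu[, 1:3] <- rec$imu[, 1:3] + matrix(rnorm(n * 3, 0, 0.02), n)
  a <- add_sync_taps(rec, amplitude = 40, at = c(100, n - 100))
  # b runs 0.1% fast: sample i of b corresponds to time i / 1.001
  pos <- seq(1, n, by = 1 / 1.001)
  b <- a
  b$imu <- apply(a$imu, 2, function(col) approx(seq_len(n), col, xout = pos)$y)
  b$angles <- apply(a$angles, 2, function(col) approx(seq_len(n), col, xout = pos)$y)
  b$missing <- rep(FALSE, length(pos))
  b$segments <- cbind(start = 1L, end = length(pos) + 1L)
  res <- synchronize(a, b)
  expect_equal(res$sync$scale, 1.001, tolerance = 2e-4)
  # post-alignment: re-detect taps on the resampled stream
  taps_b2 <- detect_taps(gaitxpop:::new_gait_recording(
    "b2", "test", res$b$imu, res$b$angles, res$b$missing, res$b$segments))
  taps_a2 <- detect_taps(res$a)
  expect_lte(max(abs(taps_a2 - taps_b2)), 1)
})
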