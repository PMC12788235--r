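# Synthetic gait generator: determinism, labeling, variance scaling, waveform
# structure, gap process and sync taps.

test_that("sample_population returns labelled, deterministic specs", {
  prof <- tiny_profile(name = "young", n = 17)
  specs <- sample_population(prof, seed = 1)
  expect_equal(nrow(specs), 17)
  expect_equal(specs$participant_id, sprintf("Y%02d", 1:17))
  expect_identical(specs, sample_population(prof, seed = 1))
  expect_false(identical(specs$cadence,
                         sample_population(prof, seed = 2)$cadence))
  expect_error(sample_population(tiny_profile(n = 1)[c()], 1))
})

test_that("heterogeneity_scale doubles -> cadence variance about 4x", {
  n <- 1000
  v <- vapply(c(1, 2), function(h) {
    specs <- sample_population(tiny_profile(name = "older", n = n,
                                            heterogeneity = h), seed = 7)
    var(specs$cadence)
  }, numeric(1))
  ratio <- v[2] / v[1]
  # Monte-Carlo oracle: var of a variance ratio at n=1000 is ~ +/-10%
  expect_gt(ratio, 3.4)
  expect_lt(ratio, 4.7)
})

test_that("default profiles encode older > preop > young heterogeneity", {
  p <- default_profiles()
  expect_equal(p$young$n_participants, 17)
  expect_equal(p$older$n_participants, 20)
  expect_equal(p$preop$n_participants, 14)
  expect_true(p$older$heterogeneity_scale > p$preop$heterogeneity_scale)
  expect_true(p$preop$heterogeneity_scale > p$young$heterogeneity_scale)
  expect_equal(p$preop$n_speed_conditions, 1)
})

test_that("left and right angles are antiphase copies when symmetric", {
  prof <- tiny_profile(n = 1, jitter = 0, noise = 0)
  spec <- sample_population(prof, 3)
  spec$asymmetry <- 0
  phase <- seq(0, 4 * pi, length.out = 400)
  ang <- gaitxpop:::angles_at_phase(spec[1, ], phase)
  ang_shift <- gaitxpop:::angles_at_phase(spec[1, ], phase + pi)
  for (j in c("hip", "knee", "ankle")) {
    expect_lt(max(abs(ang[, paste0(j, "R")] - ang_shift[, paste0(j, "L")])),
              1e-6)
  }
})

test_that("angles stay within the Fourier amplitude bound", {
  spec <- sample_population(tiny_profile(n = 1), 11)
  rec <- generate_recording(spec[1, ], 11)
  amps <- spec$amplitudes[[1]]
  mu <- spec$mean_angle[[1]]
  for (j in seq_along(gaitxpop:::JOINTS)) {
    bound <- sum(amps[, j]) + 1e-9
    dev <- abs(rec$angles[, paste0(gaitxpop:::JOINTS[j], "L")] - mu[[j]])
    expect_lte(max(dev), bound)
  }
})

test_that("cadence 120 at 100 Hz puts the stride autocorrelation peak at lag 100", {
  rec <- tiny_recording(seed = 5, duration = 10, noise = 0, jitter = 0,
                        cadence = 120)
  x <- rec$angles[, "hipL"] - mean(rec$angles[, "hipL"])
  ac <- stats::acf(x, lag.max = 130, plot = FALSE)$acf[-1]
  peak <- which.max(ac[80:130]) + 79
  expect_gte(peak, 98)
  expect_lte(peak, 102)
})

test_that("generated recordings are deterministic and bout-segmented", {
  spec <- sample_population(tiny_profile(n = 1, speeds = 3, duration = 30), 2)
  r1 <- generate_recording(spec[1, ], 9)
  r2 <- generate_recording(spec[1, ], 9)
  expect_identical(r1$imu, r2$imu)
  expect_equal(nrow(r1$segments), 3)
  expect_equal(sum(gaitxpop:::segment_lengths(r1$segments)), nrow(r1$imu))
})

test_that("gap injection is a seeded Poisson process; zero rate is identity", {
  rec <- tiny_recording(seed = 1, duration = 60)
  expect_identical(inject_gaps(rec, 0), rec)
  g1 <- inject_gaps(rec, 0.5, seed = 3)
  expect_identical(g1$missing, inject_gaps(rec, 0.5, seed = 3)$missing)
  expect_true(all(is.na(g1$imu[g1$missing, ])))
  expect_identical(g1$angles, rec$angles)  # angles untouched
})

test_that("mean gap count matches the Poisson rate over many seeds", {
  rec <- tiny_recording(seed = 2, duration = 600)
  counts <- vapply(1:100, function(s) {
    m <- inject_gaps(rec, 0.1, seed = s)$missing
    sum(m & !c(FALSE, head(m, -1)))       # run starts
  }, numeric(1))
  # 0.1/s over 600 s -> lambda = 60; SE of the mean over 100 seeds ~ 0.77
  expect_lt(abs(mean(counts) - 60), 3 * sqrt(60 / 100) + 1)
})

test_that("mark_missing places a gap exactly where asked", {
  rec <- tiny_recording(seed = 4, duration = 20)
  g <- mark_missing(rec, at = 500, len = 6)
  expect_true(all(g$missing[500:505]))
  expect_equal(sum(g$missing), 6)
})

test_that("sync taps dominate a quiet baseline and are recoverable", {
  rec <- quiet_recording(n = 1500)
  tapped <- add_sync_taps(rec, amplitude = 30)
  idx <- attr(tapped, "tap_indices")
  expect_length(idx, 2)
  mag <- sqrt(rowSums(tapped$imu[, 1:3]^2))
  expect_true(which.max(mag) %in% c(idx, idx + 1, idx - 1))
  found <- detect_taps(tapped)
  expect_true(all(abs(found - idx) <= 1))
  expect_error(add_sync_taps(rec, amplitude = 0), "positive")
  expect_error(add_sync_taps(quiet_recording(n = 100)), "4 s")
})

test_that("CSV round trip preserves signals and missingness", {
  dir <- withr::local_tempdir()
  prof <- tiny_profile(n = 2, duration = 10)
  ds <- simulate_dataset(list(prof), seed = 6, gap_rate = 0.2, taps = FALSE)
  write_recordings(ds, dir)
  back <- read_recordings(dir)
  expect_equal(back$manifest$participant_id, ds$manifest$participant_id)
  r0 <- ds$recordings[[1]]
  r1 <- back$recordings[[1]]
  expect_equal(r1$missing, r0$missing)
  expect_equal(r1$imu[!r0$missing, ], r0$imu[!r0$missing, ],
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(r1$angles, r0$angles, tolerance = 1e-10, ignore_attr = TRUE)
})
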