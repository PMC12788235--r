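# Shared fixture builders. Everything is generated in code at test time.

# small single-speed profile for fast tests
tiny_profile <- function(name = "young", n = 3, duration = 30,
                         noise = 0.05, jitter = 0.02, heterogeneity = 1,
                         speeds = 1L) {
  population_profile(
    name, n,
    cadence_mean = 110, cadence_sd = 6,
    asymmetry_mean = 0.05, asymmetry_sd = 0.03,
    phase_jitter_sd = jitter, sensor_noise_sd = noise,
    bout_duration_dist = c(duration, duration),
    n_speed_conditions = speeds,
    heterogeneity_scale = heterogeneity
  )
}

# one clean recording (no gaps) for a single participant
tiny_recording <- function(seed = 1, duration = 30, noise = 0.05,
                           jitter = 0.02, asymmetry = NULL, cadence = NULL) {
  prof <- tiny_profile(n = 1, duration = duration, noise = noise,
                       jitter = jitter)
  spec <- sample_population(prof, seed)
  if (!is.null(asymmetry)) spec$asymmetry <- asymmetry
  if (!is.null(cadence)) spec$cadence <- cadence
  generate_recording(spec[1, ], seed)
}

# a flat (quiet) recording: constant IMU baseline, linear-ramp angles
quiet_recording <- function(n = 1000, id = "Q01") {
  imu <- matrix(rep(c(0.1, -0.2, 9.8, 1, 2, 3), each = n), n, 6)
  angles <- matrix(rep(seq_len(n) / 50, 6), n, 6) +
    matrix(rep(1:6, each = n), n, 6)
  gaitxpop:::new_gait_recording(
    id, "test", imu, angles, rep(FALSE, n),
    cbind(start = 1L, end = n + 1L)
  )
}

# windowed dataset over a few tiny participants
tiny_dataset <- function(n = 3, seed = 1, duration = 30, noise = 0.05,
                         cfg = window_config(200, 10), group = "young") {
  prof <- tiny_profile(name = group, n = n, duration = duration, noise = noise)
  specs <- sample_population(prof, seed)
  recs <- lapply(seq_len(n), function(i) generate_recording(specs[i, ], seed))
  make_windows(recs, cfg)
}

# metric records with prescribed participant-average values per strategy
records_from_values <- function(ids, group, strategy, mae, r) {
  rows <- lapply(seq_along(ids), function(i) {
    vals <- as.list(c(stats::setNames(rep(mae[i], 6),
                                      paste0("mae_", gaitxpop:::ANGLE_CHANNELS)),
                      stats::setNames(rep(r[i], 6),
                                      paste0("r_", gaitxpop:::ANGLE_CHANNELS))))
    tibble::tibble(participant_id = ids[i], group = group,
                   strategy = strategy, !!!vals)
  })
  add_bilateral_averages(dplyr::bind_rows(rows))
}
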