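# Synthetic multi-population gait generator.
#
# The simulator stands in for private study recordings. Joint angles follow a
# truncated Fourier series in gait phase (K = 3 harmonics per joint); the six
# IMU channels are phase-locked harmonic mixtures (k = 1, 2) through a
# participant-specific 6 x 4 mixing matrix plus Gaussian noise. No rigid-body
# physics is claimed: the pipeline only needs a learnable, phase-locked
# coupling between sensor channels and angles.

K_HARMONICS <- 3L
# canonical left-side harmonic shape: fractions of the half range of motion
AMP_FRACTIONS <- c(0.6, 0.3, 0.1)
# baseline joint offsets in degrees
MEAN_ANGLE <- c(hip = 10, knee = 25, ankle = 0)
MEAN_ANGLE_SD <- c(hip = 3, knee = 5, ankle = 2)
# fixed per-joint base phases so the waveforms look gait-like
BASE_PSI <- list(hip = c(0.0, 0.6, 1.2), knee = c(1.0, 2.0, 0.5),
                 ankle = c(2.2, 0.8, 1.6))
SPEED_MULTIPLIERS <- c(slow = 0.8, normal = 1.0, fast = 1.2)

# nominal channel amplitudes: accelerometer in m/s^2, gyroscope in deg/s
CHANNEL_SCALE <- c(ax = 2, ay = 2, az = 2.5, gx = 40, gy = 40, gz = 50)
# each IMU channel has one dominant harmonic so the mixing is well conditioned
BASE_MIXING_PATTERN <- rbind(
  ax = c(1.0, 0.2, 0.3, 0.0),
  ay = c(0.2, 1.0, 0.0, 0.3),
  az = c(0.3, 0.0, 1.0, 0.2),
  gx = c(0.0, 0.3, 0.2, 1.0),
  gy = c(1.0, 0.0, 0.4, 0.2),
  gz = c(0.2, 1.0, 0.0, 0.4)
)

id_prefix <- function(group) {
  switch(group, young = "Y", older = "O", preop = "P",
         toupper(substr(group, 1, 1)))
}

#' Draw participant specifications from a population profile
#'
#' Samples `profile$n_participants` participant-level parameter sets: cadence,
#' per-joint Fourier amplitudes and phases (left side; the right side is the
#' left at a half-cycle phase offset with amplitudes scaled by
#' `1 - asymmetry`), an IMU mixing matrix, and a bout plan (speed multiplier
#' and duration per bout). Identical `(profile, seed)` input yields identical
#' output.
#'
#' @param profile A [population_profile()].
#' @param seed Integer seed.
#' @return A tibble of class `participant_specs`, one row per participant, with
#'   list-columns for the Fourier coefficients, mixing matrix and bout plan.
#' @export
sample_population <- function(profile, seed) {
  stopifnot(inherits(profile, "population_profile"))
  if (profile$n_participants <= 0L) abort("`n_participants` must be positive.")
  h <- profile$heterogeneity_scale
  prefix <- id_prefix(profile$name)
  specs <- purrr::map(seq_len(profile$n_participants), function(i) {
    with_seed(derive_seed(seed, profile$name, "participant", i), {
      cadence <- max(40, rnorm(1, profile$cadence_mean, profile$cadence_sd * h))
      asym <- min(1, max(0, rnorm(1, profile$asymmetry_mean,
                                  profile$asymmetry_sd * h)))
      rom <- pmax(5, rnorm(3, profile$rom_mean, profile$rom_sd * h))
      names(rom) <- JOINTS
      mean_angle <- rnorm(3, MEAN_ANGLE, MEAN_ANGLE_SD * h)
      names(mean_angle) <- JOINTS
      amps <- vapply(JOINTS, function(j) {
        (rom[[j]] / 2) * AMP_FRACTIONS * exp(rnorm(3, 0, 0.1 * h))
      }, numeric(K_HARMONICS))          # K x 3 joints
      psis <- vapply(JOINTS, function(j) {
        BASE_PSI[[j]] + rnorm(3, 0, 0.2 * h)
      }, numeric(K_HARMONICS))
      mixing <- BASE_MIXING_PATTERN * CHANNEL_SCALE +
        matrix(rnorm(24, 0, 0.15 * h), 6, 4) * CHANNEL_SCALE
      dimnames(mixing) <- list(IMU_CHANNELS, NULL)
      total <- runif(1, profile$bout_duration_dist[1], profile$bout_duration_dist[2])
      if (profile$n_speed_conditions == 3L) {
        plan <- tibble::tibble(speed = unname(SPEED_MULTIPLIERS),
                               duration = round(total / 3))
      } else {
        plan <- tibble::tibble(speed = 1.0, duration = round(total))
      }
      tibble::tibble(
        participant_id = sprintf("%s%02d", prefix, i),
        group = profile$name,
        cadence = cadence,
        asymmetry = asym,
        phase_jitter_sd = profile$phase_jitter_sd,
        sensor_noise_sd = profile$sensor_noise_sd,
        mean_angle = list(mean_angle),
        amplitudes = list(amps),
        phases = list(psis),
        mixing_matrix = list(mixing),
        bout_plan = list(plan)
      )
    })
  })
  out <- dplyr::bind_rows(specs)
  class(out) <- c("participant_specs", class(out))
  out
}

new_gait_recording <- function(participant_id, group, imu, angles, missing,
                               segments, sample_rate = SAMPLE_RATE) {
  stopifnot(nrow(imu) == nrow(angles), nrow(imu) == length(missing))
  colnames(imu) <- IMU_CHANNELS
  colnames(angles) <- ANGLE_CHANNELS
  structure(
    list(participant_id = participant_id, group = group,
         sample_rate = sample_rate, imu = imu, angles = angles,
         missing = missing, segments = segments),
    class = "gait_recording"
  )
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf(
    "<gait_recording %s (%s)> %d samples @ %d Hz, %d segment(s), %d missing\n",
    x$participant_id, x$group, nrow(x$imu), x$sample_rate,
    nrow(x$segments), sum(x$missing)
  ))
  invisible(x)
}

#' Coerce a gait recording to a tibble
#'
#' One row per sample: time, the six IMU channels, the six joint angles and
#' the missing-sample flag.
#'
#' @param x A `gait_recording`.
#' @param ... Unused.
#' @method as_tibble gait_recording
#' @export
as_tibble.gait_recording <- function(x, ...) {
  n <- nrow(x$imu)
  dplyr::bind_cols(
    tibble::tibble(t = (seq_len(n) - 1) / x$sample_rate),
    tibble::as_tibble(x$imu),
    tibble::as_tibble(x$angles),
    tibble::tibble(missing = x$missing)
  )
}

# evaluate the six joint angles at the given gait phases for one participant
angles_at_phase <- function(spec_row, phase, speed_amp = 1) {
  amps <- spec_row$amplitudes[[1]]
  psis <- spec_row$phases[[1]]
  mu <- spec_row$mean_angle[[1]]
  asym <- spec_row$asymmetry
  out <- matrix(0, length(phase), 6, dimnames = list(NULL, ANGLE_CHANNELS))
  for (j in seq_along(JOINTS)) {
    joint <- JOINTS[j]
    left <- rep(mu[[joint]], length(phase))
    right <- left
    for (k in seq_len(K_HARMONICS)) {
      a <- amps[k, j] * speed_amp
      left <- left + a * cos(k * phase + psis[k, j])
      right <- right + a * (1 - asym) * cos(k * (phase + pi) + psis[k, j])
    }
    out[, paste0(joint, "L")] <- left
    out[, paste0(joint, "R")] <- right
  }
  out
}

harmonic_basis <- function(phase) {
  cbind(cos(phase), sin(phase), cos(2 * phase), sin(2 * phase))
}

#' Generate one participant's synthetic recording
#'
#' The gait phase advances at `2 * pi * (cadence / 120) * speed` radians per
#' second (one stride per two steps) plus Brownian jitter. Joint angles are the
#' participant's Fourier series evaluated at the phase, the right leg at a
#' half-cycle offset with amplitudes scaled by `1 - asymmetry`; bout speed
#' multiplies both the phase rate and the waveform amplitudes. IMU channels are
#' the mixing matrix applied to the `(cos k phi, sin k phi)` basis (k = 1, 2)
#' plus Gaussian noise. Each bout becomes its own segment.
#'
#' @param spec_row One row of a `participant_specs` tibble.
#' @param seed Integer seed.
#' @return A `gait_recording`.
#' @export
generate_recording <- function(spec_row, seed) {
  if (nrow(spec_row) != 1L) abort("`spec_row` must be a single participant row.")
  plan <- spec_row$bout_plan[[1]]
  if (nrow(plan) == 0L) abort("empty bout plan.")
  fs <- SAMPLE_RATE
  with_seed(derive_seed(seed, spec_row$participant_id, "recording"), {
    imu_list <- list()
    ang_list <- list()
    seg_start <- integer(0)
    offset <- 0L
    for (b in seq_len(nrow(plan))) {
      n <- as.integer(round(plan$duration[b] * fs))
      speed <- plan$speed[b]
      base_rate <- 2 * pi * (spec_row$cadence / 120) * speed / fs
      incr <- base_rate + rnorm(n, 0, spec_row$phase_jitter_sd / sqrt(fs))
      phase <- runif(1, 0, 2 * pi) + cumsum(incr)
      ang <- angles_at_phase(spec_row, phase, speed_amp = speed)
      basis <- harmonic_basis(phase)
      clean <- basis %*% t(spec_row$mixing_matrix[[1]]) * speed
      noise <- matrix(rnorm(n * 6), n, 6) *
        rep(CHANNEL_SCALE * spec_row$sensor_noise_sd, each = n)
      imu_list[[b]] <- clean + noise
      ang_list[[b]] <- ang
      seg_start <- c(seg_start, offset + 1L)
      offset <- offset + n
    }
    imu <- do.call(rbind, imu_list)
    angles <- do.call(rbind, ang_list)
    seg <- cbind(start = seg_start,
                 end = c(seg_start[-1], nrow(imu) + 1L))
    new_gait_recording(spec_row$participant_id, spec_row$group,
                       imu, angles, rep(FALSE, nrow(imu)), seg)
  })
}

#' Inject random data-loss gaps into a recording
#'
#' Gap onsets arrive as a per-sample Bernoulli thinning of a Poisson process
#' with rate `gap_rate` per second; lengths are drawn from `gap_len_dist`
#' (default geometric with mean 3 frames, so both the interpolation and the
#' exclusion branch of preprocessing are exercised). Affected IMU samples are
#' set to `NA` and flagged in the missing mask; angles are untouched.
#'
#' @param rec A `gait_recording`.
#' @param gap_rate Expected gap onsets per second (0 = identity).
#' @param gap_len_dist Function `n -> n` positive integer lengths.
#' @param seed Integer seed.
#' @return The recording with gaps marked.
#' @export
inject_gaps <- function(rec, gap_rate,
                        gap_len_dist = function(n) rgeom(n, 1 / 3) + 1L,
                        seed = 0L) {
  stopifnot(inherits(rec, "gait_recording"))
  stopifnot_scalar_number(gap_rate, "gap_rate", min = 0)
  if (gap_rate == 0) return(rec)
  n <- nrow(rec$imu)
  with_seed(derive_seed(seed, rec$participant_id, "gaps"), {
    p <- gap_rate / rec$sample_rate
    starts <- which(runif(n) < p)
    lens <- if (length(starts)) as.integer(gap_len_dist(length(starts))) else integer(0)
    for (i in seq_along(starts)) {
      idx <- starts[i]:min(n, starts[i] + lens[i] - 1L)
      rec$missing[idx] <- TRUE
    }
  })
  rec$imu[rec$missing, ] <- NA_real_
  attr(rec, "n_gap_onsets") <- length(which(rec$missing & !c(FALSE, head(rec$missing, -1))))
  rec
}

#' Mark a single missing run at a known position
#'
#' Deterministic companion to [inject_gaps()], mainly for tests and examples.
#'
#' @param rec A `gait_recording`.
#' @param at First missing sample index (1-based).
#' @param len Run length in frames.
#' @return The recording with the run marked missing.
#' @export
mark_missing <- function(rec, at, len) {
  stopifnot(inherits(rec, "gait_recording"), at >= 1, len >= 1,
            at + len - 1 <= nrow(rec$imu))
  idx <- at:(at + len - 1L)
  rec$missing[idx] <- TRUE
  rec$imu[idx, ] <- NA_real_
  rec
}

#' Superimpose synchronization taps on the accelerometer channels
#'
#' Adds a short high-amplitude transient (5-sample raised-cosine pulse) to the
#' three accelerometer channels near the start and end of the recording,
#' emulating the experimenter tapping the pelvis sensor to create
#' synchronization landmarks. Tap sample indices are returned in the
#' `tap_indices` attribute.
#'
#' @param rec A `gait_recording` of at least 4 s.
#' @param amplitude Peak added acceleration (sensor units), > 0.
#' @param at Optional integer vector of tap centre indices; default 0.5 s from
#'   each end.
#' @return The recording with taps added and `attr(, "tap_indices")` set.
#' @export
add_sync_taps <- function(rec, amplitude = 30, at = NULL) {
  stopifnot(inherits(rec, "gait_recording"))
  if (amplitude <= 0) abort("`amplitude` must be positive.")
  n <- nrow(rec$imu)
  fs <- rec$sample_rate
  if (n < 4 * fs) abort("recording must be at least 4 s long to carry taps.")
  if (is.null(at)) at <- c(round(0.5 * fs), n - round(0.5 * fs))
  pulse <- amplitude * (0.5 - 0.5 * cos(2 * pi * (0:4) / 4))  # peak at centre
  for (k in at) {
    idx <- (k - 2L):(k + 2L)
    ok <- idx >= 1L & idx <= n
    rec$imu[idx[ok], 1:3] <- rec$imu[idx[ok], 1:3] + pulse[ok]
  }
  attr(rec, "tap_indices") <- as.integer(at)
  rec
}

#' Simulate a full multi-population dataset
#'
#' Draws participants for each profile, generates their recordings, optionally
#' injects data-loss gaps and adds synchronization taps.
#'
#' @param profiles Named list of [population_profile()] objects.
#' @param seed Integer seed controlling every draw.
#' @param gap_rate Gap onsets per second (see [inject_gaps()]); 0 disables.
#' @param taps Add synchronization taps (logical).
#' @return List with `recordings` (list of `gait_recording`) and `manifest`
#'   (tibble: participant_id, group, n_samples).
#' @export
simulate_dataset <- function(profiles, seed, gap_rate = 0.02, taps = TRUE) {
  specs <- dplyr::bind_rows(purrr::map(profiles, sample_population, seed = seed))
  recs <- purrr::map(seq_len(nrow(specs)), function(i) {
    rec <- generate_recording(specs[i, ], seed)
    if (gap_rate > 0) rec <- inject_gaps(rec, gap_rate, seed = seed)
    if (taps && nrow(rec$imu) >= 4 * rec$sample_rate) rec <- add_sync_taps(rec)
    rec
  })
  names(recs) <- specs$participant_id
  manifest <- tibble::tibble(
    participant_id = specs$participant_id,
    group = specs$group,
    n_samples = vapply(recs, function(r) nrow(r$imu), integer(1))
  )
  list(recordings = recs, manifest = manifest, specs = specs)
}

#' Write recordings to per-participant CSV files
#'
#' Columns: `t, ax, ay, az, gx, gy, gz, hipL, hipR, kneeL, kneeR, ankleL,
#' ankleR`; missing IMU samples are written as empty fields. A `manifest.csv`
#' (participant_id, group, n_samples, file) indexes the directory.
#'
#' @param dataset Result of [simulate_dataset()], or a list of recordings.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_recordings <- function(dataset, dir) {
  recs <- if (!is.null(dataset$recordings)) dataset$recordings else dataset
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- purrr::map(recs, function(rec) {
    df <- as_tibble.gait_recording(rec)
    df$missing <- NULL
    file <- paste0(rec$participant_id, ".csv")
    write.csv(df, file.path(dir, file), row.names = FALSE, na = "")
    tibble::tibble(participant_id = rec$participant_id, group = rec$group,
                   n_samples = nrow(rec$imu), file = file)
  })
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a directory of recordings written by [write_recordings()]
#'
#' Missing IMU fields become the missing mask; segments are reconstructed as
#' the maximal runs of valid samples (bout boundaries are not stored in the
#' CSV; preprocessing re-derives segments anyway).
#'
#' @param dir Directory containing `manifest.csv` and per-participant CSVs.
#' @return List with `recordings` and `manifest`.
#' @export
read_recordings <- function(dir) {
  manifest <- tibble::as_tibble(read.csv(file.path(dir, "manifest.csv")))
  recs <- purrr::pmap(manifest, function(participant_id, group, n_samples, file) {
    df <- read.csv(file.path(dir, file))
    imu <- as.matrix(df[IMU_CHANNELS])
    angles <- as.matrix(df[ANGLE_CHANNELS])
    missing <- rowSums(is.na(imu)) > 0
    seg <- segments_from_mask(!missing)
    new_gait_recording(participant_id, group, imu, angles, missing, seg)
  })
  names(recs) <- manifest$participant_id
  list(recordings = recs, manifest = manifest)
}
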