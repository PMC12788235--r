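#' Population profile for synthetic gait generation
#'
#' A profile describes the distribution of gait parameters within one study
#' population. Participant-level parameters are drawn from these distributions
#' by [sample_population()]; `heterogeneity_scale` multiplies every
#' between-participant standard deviation, so the parameter *variance* grows
#' with its square.
#'
#' @param name Population label: `"young"`, `"older"`, `"preop"` or a custom
#'   label.
#' @param n_participants Number of participants to simulate.
#' @param cadence_mean,cadence_sd Cadence distribution in steps per minute.
#' @param rom_mean,rom_sd Named length-3 vectors (`hip`, `knee`, `ankle`):
#'   peak-to-peak range of motion in degrees.
#' @param asymmetry_mean,asymmetry_sd Left/right amplitude asymmetry,
#'   dimensionless in `[0, 1]` (0 = symmetric).
#' @param phase_jitter_sd Standard deviation of the per-step random phase
#'   perturbation, radians.
#' @param sensor_noise_sd Additive Gaussian noise on the IMU channels, as a
#'   fraction of each channel's nominal amplitude (arbitrary sensor units).
#' @param bout_duration_dist Length-2 vector `(min, max)` of the total walking
#'   duration in seconds.
#' @param n_speed_conditions 3 for self-selected slow/normal/fast bouts, 1 for a
#'   single comfortable-speed bout.
#' @param heterogeneity_scale Dimensionless multiplier (> 0) on all
#'   between-participant standard deviations.
#' @return An object of class `population_profile`.
#' @seealso [default_profiles()] for the three study populations.
#' @export
population_profile <- function(name,
                               n_participants,
                               cadence_mean = 110,
                               cadence_sd = 6,
                               rom_mean = c(hip = 40, knee = 60, ankle = 25),
                               rom_sd = c(hip = 4, knee = 6, ankle = 2.5),
                               asymmetry_mean = 0.05,
                               asymmetry_sd = 0.03,
                               phase_jitter_sd = 0.02,
                               sensor_noise_sd = 0.05,
                               bout_duration_dist = c(180, 600),
                               n_speed_conditions = 3,
                               heterogeneity_scale = 1) {
  if (!is.character(name) || length(name) != 1L) abort("`name` must be a single label.")
  stopifnot_scalar_number(n_participants, "n_participants", min = 1)
  stopifnot_scalar_number(cadence_mean, "cadence_mean", min = 0, strict_min = TRUE)
  stopifnot_scalar_number(cadence_sd, "cadence_sd", min = 0)
  stopifnot_scalar_number(asymmetry_sd, "asymmetry_sd", min = 0)
  stopifnot_scalar_number(phase_jitter_sd, "phase_jitter_sd", min = 0)
  stopifnot_scalar_number(sensor_noise_sd, "sensor_noise_sd", min = 0)
  stopifnot_scalar_number(heterogeneity_scale, "heterogeneity_scale",
                          min = 0, strict_min = TRUE)
  rom_mean <- rom_mean[JOINTS]
  rom_sd <- rom_sd[JOINTS]
  if (anyNA(rom_mean) || any(rom_mean <= 0)) {
    abort("`rom_mean` must name positive values for hip, knee and ankle.")
  }
  if (anyNA(rom_sd) || any(rom_sd < 0)) {
    abort("`rom_sd` must name non-negative values for hip, knee and ankle.")
  }
  if (length(bout_duration_dist) != 2L || any(bout_duration_dist <= 0) ||
      bout_duration_dist[1] > bout_duration_dist[2]) {
    abort("`bout_duration_dist` must be (min, max) with 0 < min <= max.")
  }
  if (!n_speed_conditions %in% c(1, 3)) {
    abort("`n_speed_conditions` must be 1 or 3.")
  }
  structure(
    list(
      name = name,
      n_participants = as.integer(n_participants),
      cadence_mean = cadence_mean, cadence_sd = cadence_sd,
      rom_mean = rom_mean, rom_sd = rom_sd,
      asymmetry_mean = asymmetry_mean, asymmetry_sd = asymmetry_sd,
      phase_jitter_sd = phase_jitter_sd,
      sensor_noise_sd = sensor_noise_sd,
      bout_duration_dist = as.numeric(bout_duration_dist),
      n_speed_conditions = as.integer(n_speed_conditions),
      heterogeneity_scale = heterogeneity_scale
    ),
    class = "population_profile"
  )
}

#' Default profiles for the three study populations
#'
#' Young adults (n = 17) walk three bouts at self-selected slow/normal/fast
#' speeds; older adults (n = 20) do the same with slower cadence, more
#' asymmetry and the largest between-participant heterogeneity; pre-operative
#' hip-osteoarthritis patients (n = 14) walk one shorter comfortable-speed bout
#' with reduced hip range of motion, strong asymmetry and intermediate
#' heterogeneity. Sizes follow the study populations; gait parameters are
#' documented simulator plumbing, not measured values.
#'
#' @param durations Optional length-2 override of `bout_duration_dist`
#'   (seconds) applied to every profile, to scale datasets down.
#' @return Named list of [population_profile()] objects.
#' @export
default_profiles <- function(durations = NULL) {
  p <- list(
    young = population_profile(
      "young", 17,
      cadence_mean = 113, cadence_sd = 6,
      rom_mean = c(hip = 40, knee = 60, ankle = 25),
      asymmetry_mean = 0.04, asymmetry_sd = 0.02,
      phase_jitter_sd = 0.015, sensor_noise_sd = 0.05,
      bout_duration_dist = c(300, 600), n_speed_conditions = 3,
      heterogeneity_scale = 1
    ),
    older = population_profile(
      "older", 20,
      cadence_mean = 105, cadence_sd = 8,
      rom_mean = c(hip = 36, knee = 55, ankle = 23),
      asymmetry_mean = 0.08, asymmetry_sd = 0.04,
      phase_jitter_sd = 0.03, sensor_noise_sd = 0.06,
      bout_duration_dist = c(300, 600), n_speed_conditions = 3,
      heterogeneity_scale = 2
    ),
    preop = population_profile(
      "preop", 14,
      cadence_mean = 96, cadence_sd = 9,
      rom_mean = c(hip = 28, knee = 48, ankle = 20),
      asymmetry_mean = 0.2, asymmetry_sd = 0.08,
      phase_jitter_sd = 0.05, sensor_noise_sd = 0.08,
      bout_duration_dist = c(60, 300), n_speed_conditions = 1,
      heterogeneity_scale = 1.5
    )
  )
  if (!is.null(durations)) {
    p <- lapply(p, function(x) {
      x$bout_duration_dist <- as.numeric(durations)
      x
    })
  }
  p
}

#' Desk-scale validation profiles
#'
#' Two canonical small study designs used to validate the pipeline end to end
#' on a CPU.
#'
#' `learnability_profile()` is a single low-noise, low-heterogeneity
#' population: with sensor noise near zero and nearly shared participant
#' parameters, the angles are close to a deterministic function of the IMU
#' phase harmonics, so a correctly wired pipeline must reach low test error —
#' failures indicate leakage, broken standardization or a defective model, not
#' hard data.
#'
#' `heterogeneity_benchmark_profiles()` is a three-population design (n = 5
#' each, one 60 s bout) whose "older" group carries large between-participant
#' heterogeneity: the regime in which pooling all populations for training is
#' expected to help the heterogeneous group relative to within-population
#' training.
#'
#' @param n Participants per population.
#' @param duration Bout duration in seconds.
#' @return A [population_profile()] (or named list of three).
#' @export
learnability_profile <- function(n = 5, duration = 60) {
  population_profile(
    "young", n,
    cadence_mean = 110, cadence_sd = 6,
    sensor_noise_sd = 0.01, phase_jitter_sd = 0.01,
    bout_duration_dist = c(duration, duration), n_speed_conditions = 1,
    heterogeneity_scale = 0.3
  )
}

#' @rdname learnability_profile
#' @export
heterogeneity_benchmark_profiles <- function(n = 5, duration = 60) {
  mk <- function(name, cad, noise, jit, het) population_profile(
    name, n, cadence_mean = cad, sensor_noise_sd = noise,
    phase_jitter_sd = jit, bout_duration_dist = c(duration, duration),
    n_speed_conditions = 1, heterogeneity_scale = het
  )
  list(young = mk("young", 113, 0.05, 0.015, 1),
       older = mk("older", 105, 0.06, 0.03, 2.5),
       preop = mk("preop", 96, 0.08, 0.05, 1.5))
}

#' Read population profiles from a YAML file
#'
#' Each top-level key is a profile name; values are passed to
#' [population_profile()].
#'
#' @param path YAML file path.
#' @return Named list of profiles.
#' @export
read_profiles <- function(path) {
  raw <- yaml::read_yaml(path)
  purrr::imap(raw, function(fields, nm) {
    fields$name <- fields$name %||% nm
    for (v in c("rom_mean", "rom_sd")) {
      if (!is.null(fields[[v]])) fields[[v]] <- unlist(fields[[v]])
    }
    do.call(population_profile, fields)
  })
}

#' @export
print.population_profile <- function(x, ...) {
  cat(sprintf(
    "<population_profile '%s'> n=%d, cadence %.0f+/-%.0f spm, %d speed(s), heterogeneity x%.1f\n",
    x$name, x$n_participants, x$cadence_mean, x$cadence_sd,
    x$n_speed_conditions, x$heterogeneity_scale
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
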