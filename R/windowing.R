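# Sliding-window segmentation and leakage-free standardization.

#' Sliding-window configuration
#'
#' Defaults follow the study protocol: 200-sample (2 s) windows advanced by 10
#' samples (100 ms), i.e. 95% overlap between consecutive windows, with the
#' six joint angles at each window's final time step as the regression target
#' (only past and current sensor data are used).
#'
#' @param window_len Window length in frames.
#' @param stride Step between consecutive window ends, frames.
#' @return An object of class `window_config`.
#' @export
window_config <- function(window_len = 200L, stride = 10L) {
  stopifnot_scalar_number(window_len, "window_len", min = 1)
  stopifnot_scalar_number(stride, "stride", min = 1)
  if (stride > window_len) abort("`stride` must satisfy 0 < stride <= window_len.")
  structure(list(window_len = as.integer(window_len), stride = as.integer(stride)),
            class = "window_config")
}

#' Fraction of overlap between consecutive windows
#'
#' @param cfg A [window_config()].
#' @return `(window_len - stride) / window_len`.
#' @export
window_overlap <- function(cfg) {
  (cfg$window_len - cfg$stride) / cfg$window_len
}

# number of windows a segment of length n yields
n_windows_for <- function(n, cfg) {
  if (n < cfg$window_len) 0L else (n - cfg$window_len) %/% cfg$stride + 1L
}

#' Cut a recording into fixed-length input windows with final-step targets
#'
#' Windows are enumerated left-to-right inside each segment and never cross a
#' segment boundary (interpolation beyond the allowed gap length is forbidden,
#' so continuity across a boundary is undefined). Each window's target is the
#' six-angle vector at its last frame; no future samples are used.
#'
#' @param recs A `gait_recording` or list of them.
#' @param cfg A [window_config()].
#' @return An object of class `window_dataset`: `inputs` array
#'   `(6, window_len, N)` in sensor units, `targets` matrix `(N, 6)` in
#'   degrees, and `provenance` tibble (participant_id, group, segment,
#'   end_frame) with one row per window.
#' @export
make_windows <- function(recs, cfg = window_config()) {
  if (inherits(recs, "gait_recording")) recs <- list(recs)
  W <- cfg$window_len
  inputs <- list()
  targets <- list()
  prov <- list()
  for (rec in recs) {
    seg <- rec$segments
    for (s in seq_len(nrow(seg))) {
      lo <- seg[s, "start"]; hi <- seg[s, "end"] - 1L
      nw <- n_windows_for(hi - lo + 1L, cfg)
      if (nw == 0L) next
      ends <- lo + W - 1L + (seq_len(nw) - 1L) * cfg$stride
      x <- array(0, c(6L, W, nw))
      for (i in seq_len(nw)) {
        x[, , i] <- t(rec$imu[(ends[i] - W + 1L):ends[i], , drop = FALSE])
      }
      inputs[[length(inputs) + 1L]] <- x
      targets[[length(targets) + 1L]] <- rec$angles[ends, , drop = FALSE]
      prov[[length(prov) + 1L]] <- tibble::tibble(
        participant_id = rec$participant_id, group = rec$group,
        segment = s, end_frame = ends
      )
    }
  }
  n_total <- sum(vapply(inputs, function(x) dim(x)[3], integer(1)))
  X <- array(0, c(6L, W, n_total))
  at <- 0L
  for (x in inputs) {
    k <- dim(x)[3]
    if (k) X[, , at + seq_len(k)] <- x
    at <- at + k
  }
  structure(
    list(
      inputs = X,
      targets = if (length(targets)) do.call(rbind, targets) else
        matrix(0, 0, 6, dimnames = list(NULL, ANGLE_CHANNELS)),
      provenance = if (length(prov)) dplyr::bind_rows(prov) else
        tibble::tibble(participant_id = character(), group = character(),
                       segment = integer(), end_frame = integer()),
      config = cfg
    ),
    class = "window_dataset"
  )
}

#' @export
print.window_dataset <- function(x, ...) {
  cat(sprintf(
    "<window_dataset> %d windows of %d frames (stride %d), %d participant(s)\n",
    n_windows(x), x$config$window_len, x$config$stride,
    dplyr::n_distinct(x$provenance$participant_id)
  ))
  invisible(x)
}

#' Number of windows in a dataset
#' @param ds A `window_dataset`.
#' @export
n_windows <- function(ds) dim(ds$inputs)[3]

#' Subset a window dataset by window index or participant
#'
#' @param ds A `window_dataset`.
#' @param idx Integer window indices, or
#' @param participants Character vector of participant ids (used if `idx` is
#'   missing).
#' @return The subsetted `window_dataset`.
#' @export
subset_windows <- function(ds, idx = NULL, participants = NULL) {
  if (is.null(idx)) {
    stopifnot(!is.null(participants))
    idx <- which(ds$provenance$participant_id %in% participants)
  }
  structure(
    list(inputs = ds$inputs[, , idx, drop = FALSE],
         targets = ds$targets[idx, , drop = FALSE],
         provenance = ds$provenance[idx, ],
         config = ds$config),
    class = "window_dataset"
  )
}

#' Fit a z-score standardizer on training participants only
#'
#' Per-channel means and standard deviations for the 6 input channels (over
#' every sample of every training window) and the 6 target channels (over
#' training window targets). Statistics are computed exclusively from windows
#' whose provenance participant is in the training set, then applied unchanged
#' to validation and test data, preventing leakage.
#'
#' @param ds A `window_dataset`.
#' @param training_participants Character vector of participant ids.
#' @return An object of class `standardizer` with fields `input_mean`,
#'   `input_sd`, `target_mean`, `target_sd`.
#' @export
fit_standardizer <- function(ds, training_participants) {
  if (length(training_participants) == 0L) abort("training set is empty.")
  idx <- which(ds$provenance$participant_id %in% training_participants)
  if (length(idx) == 0L) abort("no windows belong to the training participants.")
  x <- ds$inputs[, , idx, drop = FALSE]
  xm <- matrix(x, nrow = 6L)             # channels x (len * n)
  input_mean <- rowMeans(xm)
  input_sd <- sqrt(rowMeans(xm^2) - input_mean^2)
  y <- ds$targets[idx, , drop = FALSE]
  target_mean <- colMeans(y)
  target_sd <- apply(y, 2, function(v) sqrt(mean(v^2) - mean(v)^2))
  check <- function(sds, names, what) {
    bad <- which(sds <= .Machine$double.eps^0.5)
    if (length(bad)) {
      abort(sprintf("degenerate %s channel(s) with zero variance: %s",
                    what, paste(names[bad], collapse = ", ")))
    }
  }
  check(input_sd, IMU_CHANNELS, "input")
  check(target_sd, ANGLE_CHANNELS, "target")
  structure(
    list(input_mean = input_mean, input_sd = input_sd,
         target_mean = target_mean, target_sd = target_sd),
    class = "standardizer"
  )
}

#' Apply a fitted standardizer
#'
#' @param x A `window_dataset` (both inputs and targets are standardized), an
#'   input array `(6, L, N)`, or a target matrix `(N, 6)`.
#' @param st A fitted `standardizer`.
#' @param what `"inputs"` or `"targets"`; required for bare arrays/matrices.
#' @return Standardized object of the same shape.
#' @export
apply_standardizer <- function(x, st, what = NULL) {
  stopifnot(inherits(st, "standardizer"))
  if (inherits(x, "window_dataset")) {
    x$inputs <- apply_standardizer(x$inputs, st, "inputs")
    x$targets <- apply_standardizer(x$targets, st, "targets")
    return(x)
  }
  if (identical(what, "inputs")) {
    if (dim(x)[1] != 6L) abort("input array must have 6 channels.")
    (x - st$input_mean) / st$input_sd   # recycles over dim 1
  } else if (identical(what, "targets")) {
    if (ncol(x) != 6L) abort("target matrix must have 6 columns.")
    sweep(sweep(x, 2, st$target_mean), 2, st$target_sd, "/")
  } else {
    abort("specify `what` = \"inputs\" or \"targets\" for bare arrays.")
  }
}

#' Invert standardization (predictions back to physical units)
#'
#' `invert_standardizer(apply_standardizer(x, st, what), st, what)` is the
#' identity to floating-point tolerance; predictions are always inverted back
#' to degrees before metrics are computed.
#'
#' @inheritParams apply_standardizer
#' @export
invert_standardizer <- function(x, st, what = "targets") {
  stopifnot(inherits(st, "standardizer"))
  if (identical(what, "inputs")) {
    if (dim(x)[1] != 6L) abort("input array must have 6 channels.")
    x * st$input_sd + st$input_mean
  } else {
    if (ncol(x) != 6L) abort("target matrix must have 6 columns.")
    sweep(sweep(x, 2, st$target_sd, "*"), 2, st$target_mean, "+")
  }
}
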