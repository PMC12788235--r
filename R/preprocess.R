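# Cleaning and synchronization of raw recordings.

#' Interpolate short data-loss gaps and exclude long ones
#'
#' Runs of missing IMU samples of length `<= max_gap` frames that lie strictly
#' inside valid data are filled per channel by linear interpolation between the
#' bounding valid samples. Longer runs stay excluded and split the recording
#' into separate segments; sliding windows never cross a segment boundary.
#' Runs touching the start or end of a segment have only one anchor and are
#' always excluded. Existing segment boundaries (e.g. bout edges) are
#' preserved: interpolation never bridges them.
#'
#' @param rec A `gait_recording` with a missing mask.
#' @param max_gap Longest run length (frames) that is interpolated; default 5
#'   frames = 50 ms at 100 Hz.
#' @return The recording with gaps filled, the mask updated, and `segments`
#'   recomputed to cover exactly the valid samples. The number of interpolated
#'   frames is recorded in `attr(, "n_interpolated")`. A recording left with no
#'   valid samples yields an empty segment list (flagged with a warning, not an
#'   error).
#' @export
interpolate_gaps <- function(rec, max_gap = 5L) {
  stopifnot(inherits(rec, "gait_recording"))
  stopifnot_scalar_number(max_gap, "max_gap", min = 0)
  n <- nrow(rec$imu)
  bounds <- rec$segments
  if (nrow(bounds) == 0L) bounds <- cbind(start = 1L, end = n + 1L)
  n_filled <- 0L
  for (s in seq_len(nrow(bounds))) {
    lo <- bounds[s, "start"]; hi <- bounds[s, "end"] - 1L
    if (hi < lo) next
    miss <- rec$missing[lo:hi]
    if (!any(miss)) next
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      len <- r$lengths[i]
      a <- lo + starts[i] - 1L   # absolute gap start
      b <- lo + ends[i] - 1L     # absolute gap end
      interior <- a > lo && b < hi
      if (len <= max_gap && interior) {
        left <- a - 1L; right <- b + 1L
        w <- (seq.int(a, b) - left) / (right - left)
        for (ch in seq_len(ncol(rec$imu))) {
          rec$imu[a:b, ch] <- rec$imu[left, ch] * (1 - w) + rec$imu[right, ch] * w
        }
        rec$missing[a:b] <- FALSE
        n_filled <- n_filled + len
      }
    }
  }
  # valid = not missing, intersected with the original segment cover
  valid <- !rec$missing
  covered <- rep(FALSE, n)
  for (s in seq_len(nrow(bounds))) {
    if (bounds[s, "end"] > bounds[s, "start"]) {
      covered[bounds[s, "start"]:(bounds[s, "end"] - 1L)] <- TRUE
    }
  }
  # carry a break marker at original boundaries by segmenting per bound
  seg_list <- list()
  for (s in seq_len(nrow(bounds))) {
    lo <- bounds[s, "start"]; hi <- bounds[s, "end"] - 1L
    if (hi < lo) next
    sub <- segments_from_mask(valid[lo:hi] & covered[lo:hi])
    if (nrow(sub)) {
      sub[, "start"] <- sub[, "start"] + lo - 1L
      sub[, "end"] <- sub[, "end"] + lo - 1L
      seg_list[[length(seg_list) + 1L]] <- sub
    }
  }
  rec$segments <- if (length(seg_list)) do.call(rbind, seg_list) else
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
  if (nrow(rec$segments) == 0L) {
    warn(sprintf("recording %s has no valid samples after gap exclusion",
                 rec$participant_id))
  }
  attr(rec, "n_interpolated") <- n_filled
  rec
}

#' Detect synchronization taps in an acceleration stream
#'
#' Searches the leading and trailing `search_window` seconds of the
#' acceleration-magnitude signal for the largest excursion above
#' `median + threshold_k * MAD`; one index per window is returned. The
#' median/MAD baseline is robust to the gait signal itself.
#'
#' @param accel 3-column acceleration matrix (or a `gait_recording`).
#' @param search_window Seconds searched at each end (default 2).
#' @param threshold_k Robust-SD multiplier (default 8).
#' @param sample_rate Hz (taken from the recording if one is given).
#' @return Sorted integer vector of two tap indices.
#' @export
detect_taps <- function(accel, search_window = 2, threshold_k = 8,
                        sample_rate = SAMPLE_RATE) {
  if (inherits(accel, "gait_recording")) {
    sample_rate <- accel$sample_rate
    accel <- accel$imu[, 1:3]
  }
  n <- nrow(accel)
  w <- round(search_window * sample_rate)
  if (n <= 2 * w) abort("sequence must be longer than twice the search window.")
  mag <- sqrt(rowSums(accel^2, na.rm = TRUE))
  thr <- median(mag, na.rm = TRUE) + threshold_k * stats::mad(mag, na.rm = TRUE)
  find_in <- function(idx) {
    m <- mag[idx]
    if (all(is.na(m)) || max(m, na.rm = TRUE) <= thr) {
      abort("tap not found: no excursion above the robust threshold.")
    }
    idx[which.max(m)]
  }
  sort(c(find_in(seq_len(w)), find_in(seq.int(n - w + 1L, n))))
}

#' Synchronize two recordings via their tap transients
#'
#' The offset is taken from first-tap alignment and a linear drift factor from
#' the ratio of the inter-tap spans; stream `b` is resampled (linear
#' interpolation) onto stream `a`'s time base and both are trimmed to the
#' common support.
#'
#' @param rec_a,rec_b `gait_recording` objects carrying detectable start and
#'   end taps.
#' @param ... Passed to [detect_taps()].
#' @return List with `sync` (offset in samples, scale, tap indices of both
#'   streams) and `a`, `b`: the aligned recordings.
#' @export
synchronize <- function(rec_a, rec_b, ...) {
  taps_a <- detect_taps(rec_a, ...)
  taps_b <- detect_taps(rec_b, ...)
  offset <- taps_b[1] - taps_a[1]
  span_a <- diff(taps_a)
  span_b <- diff(taps_b)
  scale <- span_b / span_a
  if (scale <= 0) abort("degenerate tap spans; cannot synchronize.")
  na <- nrow(rec_a$imu)
  # sample b at positions taps_b[1] + (i - taps_a[1]) * scale, i on a's base
  pos <- taps_b[1] + (seq_len(na) - taps_a[1]) * scale
  keep <- pos >= 1 & pos <= nrow(rec_b$imu)
  resample <- function(mat) {
    apply(mat, 2, function(col) approx(seq_along(col), col, xout = pos[keep],
                                       rule = 1)$y)
  }
  b <- rec_b
  b$imu <- resample(rec_b$imu)
  b$angles <- resample(rec_b$angles)
  b$missing <- rec_b$missing[pmin(pmax(round(pos[keep]), 1L), nrow(rec_b$imu))]
  b$segments <- segments_from_mask(!b$missing)
  a <- rec_a
  a$imu <- rec_a$imu[keep, , drop = FALSE]
  a$angles <- rec_a$angles[keep, , drop = FALSE]
  a$missing <- rec_a$missing[keep]
  a$segments <- segments_from_mask(!a$missing)
  colnames(b$imu) <- IMU_CHANNELS; colnames(b$angles) <- ANGLE_CHANNELS
  list(
    sync = list(offset = offset, scale = scale,
                tap_indices_a = taps_a, tap_indices_b = taps_b),
    a = a, b = b
  )
}

#' @importFrom stats approx mad
NULL
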