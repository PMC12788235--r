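# Per-participant, per-joint evaluation in physical units, and the
# aggregations behind the group tables and boxplot summaries.

#' Per-participant MAE and Pearson R in degrees
#'
#' For every participant and joint-side channel, MAE is the mean absolute
#' error over all of that participant's test windows and R is the Pearson
#' correlation over the same window-end points (predictions must already be in
#' degrees). A constant truth or prediction channel leaves R undefined; it is
#' flagged missing with a warning and excluded from averages rather than
#' biased to zero. Bilateral joint values are the mean of left and right; the
#' participant average is the mean over the six joint-sides.
#'
#' @param predictions,truths N x 6 matrices in degrees (columns `hipL`,
#'   `hipR`, `kneeL`, `kneeR`, `ankleL`, `ankleR`).
#' @param provenance Tibble with one row per window; must contain
#'   `participant_id` and `group`.
#' @param strategy Strategy label stored with the records (`"within"` or
#'   `"cross"`).
#' @return A tibble of class `metric_records`, one row per participant, with
#'   `mae_<channel>` / `r_<channel>` columns plus bilateral (`mae_hip`, ...)
#'   and participant-average (`mae_avg`, `r_avg`) columns.
#' @export
compute_metrics <- function(predictions, truths, provenance,
                            strategy = "within") {
  stopifnot(nrow(predictions) == nrow(truths),
            nrow(predictions) == nrow(provenance))
  df <- tibble::tibble(participant_id = provenance$participant_id,
                       group = provenance$group)
  rows <- df |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$participant_id, .data$group) |>
    dplyr::summarise(.rows = list(.data$.row), .groups = "drop")
  recs <- purrr::pmap(rows, function(participant_id, group, .rows) {
    p <- predictions[.rows, , drop = FALSE]
    t_ <- truths[.rows, , drop = FALSE]
    mae <- colMeans(abs(p - t_))
    r <- vapply(seq_len(6), function(j) {
      if (length(.rows) < 2L || sd(t_[, j]) == 0 || sd(p[, j]) == 0) {
        NA_real_
      } else {
        cor(p[, j], t_[, j])
      }
    }, numeric(1))
    if (anyNA(r)) {
      warn(sprintf("participant %s: R undefined on %d channel(s) (constant series); excluded from averages",
                   participant_id, sum(is.na(r))))
    }
    names(mae) <- paste0("mae_", ANGLE_CHANNELS)
    names(r) <- paste0("r_", ANGLE_CHANNELS)
    tibble::tibble(participant_id = participant_id, group = group,
                   strategy = strategy, !!!as.list(mae), !!!as.list(r))
  })
  add_bilateral_averages(dplyr::bind_rows(recs))
}

#' Add bilateral and participant-average columns to metric records
#'
#' `mae_hip = mean(mae_hipL, mae_hipR)` etc., and `mae_avg` is the mean of the
#' six joint-side values (ditto for R); missing channels are excluded from the
#' means. Equal-weight means make the participant average identical whether
#' taken over the six joint-sides or the three bilateral values.
#'
#' @param records Tibble with `mae_<channel>` and `r_<channel>` columns.
#' @return The records with `mae_hip/knee/ankle/avg` and `r_...` columns.
#' @export
add_bilateral_averages <- function(records) {
  for (m in c("mae", "r")) {
    for (j in JOINTS) {
      lr <- as.matrix(records[paste0(m, "_", j, c("L", "R"))])
      records[[paste0(m, "_", j)]] <- rowMeans(lr, na.rm = TRUE)
    }
    six <- as.matrix(records[paste0(m, "_", ANGLE_CHANNELS)])
    records[[paste0(m, "_avg")]] <- rowMeans(six, na.rm = TRUE)
  }
  records <- dplyr::mutate(records, dplyr::across(
    dplyr::where(is.numeric), function(x) ifelse(is.nan(x), NA_real_, x)))
  class(records) <- unique(c("metric_records", class(records)))
  records
}

#' Group-level joint-specific tables
#'
#' Reproduces the layout of the joint-specific comparison tables: for each
#' group and metric, the mean over participants of the bilateral hip, knee and
#' ankle values and of the participant average, per strategy, with a
#' `delta = cross - within` column. Participants missing one strategy are
#' excluded pairwise with a warning.
#'
#' @param records `metric_records` containing both strategies.
#' @return Tibble: group, metric, joint (hip/knee/ankle/avg), within, cross,
#'   delta.
#' @export
aggregate_group <- function(records) {
  strategies <- unique(records$strategy)
  long <- records |>
    tidyr::pivot_longer(dplyr::matches("^(mae|r)_(hip|knee|ankle|avg)$"),
                        names_to = c("metric", "joint"), names_sep = "_") |>
    dplyr::select("participant_id", "group", "strategy", "metric", "joint",
                  "value")
  if (all(c("within", "cross") %in% strategies)) {
    paired <- long |>
      tidyr::pivot_wider(names_from = "strategy", values_from = "value")
    unpaired <- paired |>
      dplyr::filter(is.na(.data$within) | is.na(.data$cross)) |>
      dplyr::distinct(.data$participant_id)
    if (nrow(unpaired)) {
      warn(sprintf("participant(s) missing a strategy excluded pairwise: %s",
                   paste(unpaired$participant_id, collapse = ", ")))
      paired <- dplyr::filter(paired, !.data$participant_id %in%
                                unpaired$participant_id)
    }
    paired |>
      dplyr::group_by(.data$group, .data$metric, .data$joint) |>
      dplyr::summarise(within = mean(.data$within, na.rm = TRUE),
                       cross = mean(.data$cross, na.rm = TRUE),
                       .groups = "drop") |>
      dplyr::mutate(delta = .data$cross - .data$within)
  } else {
    long |>
      dplyr::group_by(.data$group, .data$metric, .data$joint, .data$strategy) |>
      dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                       .groups = "drop")
  }
}

#' Per-participant strategy differences
#'
#' `delta_mae = mae_cross - mae_within` (negative = cross-population training
#' improved the participant) and `delta_r = r_cross - r_within` (positive =
#' improvement), computed on the participant-average metrics. Participants
#' missing a strategy are skipped with a warning.
#'
#' @param records `metric_records` containing both strategies.
#' @return Tibble: participant_id, group, mae_within, mae_cross, delta_mae,
#'   r_within, r_cross, delta_r.
#' @export
participant_deltas <- function(records) {
  wide <- records |>
    dplyr::select("participant_id", "group", "strategy", "mae_avg", "r_avg") |>
    tidyr::pivot_wider(names_from = "strategy",
                       values_from = c("mae_avg", "r_avg"))
  need <- c("mae_avg_within", "mae_avg_cross", "r_avg_within", "r_avg_cross")
  miss <- setdiff(need, names(wide))
  if (length(miss)) abort("records must contain both strategies.")
  bad <- wide$participant_id[!stats::complete.cases(wide[need])]
  if (length(bad)) {
    warn(sprintf("participant(s) missing a strategy skipped: %s",
                 paste(bad, collapse = ", ")))
    wide <- wide[!wide$participant_id %in% bad, ]
  }
  wide |>
    dplyr::transmute(
      participant_id = .data$participant_id, group = .data$group,
      mae_within = .data$mae_avg_within, mae_cross = .data$mae_avg_cross,
      delta_mae = .data$mae_avg_cross - .data$mae_avg_within,
      r_within = .data$r_avg_within, r_cross = .data$r_avg_cross,
      delta_r = .data$r_avg_cross - .data$r_avg_within
    ) |>
    dplyr::arrange(.data$group, .data$participant_id)
}

#' Tukey boxplot statistics
#'
#' Quartiles by linear interpolation between order statistics (the common
#' plotting default; outlier counts depend on this choice), whiskers at the
#' most extreme observations within 1.5 x IQR of the quartiles, outliers
#' beyond.
#'
#' @param values Numeric vector (length >= 1; NAs dropped).
#' @return List: median, q1, q3, iqr, whisker_lo, whisker_hi, outliers.
#' @export
boxplot_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) abort("no values supplied.")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
       whisker_lo = min(values[inside]), whisker_hi = max(values[inside]),
       outliers = sort(values[!inside]))
}

#' Select representative participants per group
#'
#' Per group: `best` (most negative `delta_mae`), `worst` (most positive),
#' and `median` (within-population MAE closest to the group median; ties
#' break to the lowest participant id). When a group contains both improved
#' (`delta_mae < 0`) and degraded (`delta_mae > 0`) participants and
#' `split_heterogeneous` is set, the participant closest to each subgroup's
#' median within-population MAE is also reported.
#'
#' @param deltas A [participant_deltas()] tibble.
#' @param split_heterogeneous Also report improved/degraded subgroup medians.
#' @return Tibble: group, role, participant_id, mae_within, delta_mae.
#' @export
select_representatives <- function(deltas, split_heterogeneous = FALSE) {
  closest_to_median <- function(df) {
    med <- median(df$mae_within)
    df <- df[order(abs(df$mae_within - med), df$participant_id), ]
    df[1, ]
  }
  out <- deltas |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(df, key) {
      picks <- dplyr::bind_rows(
        dplyr::mutate(df[which.min(df$delta_mae), ], role = "best"),
        dplyr::mutate(closest_to_median(df), role = "median"),
        dplyr::mutate(df[which.max(df$delta_mae), ], role = "worst")
      )
      if (split_heterogeneous) {
        improved <- df[df$delta_mae < 0, ]
        degraded <- df[df$delta_mae > 0, ]
        if (nrow(improved) && nrow(degraded)) {
          picks <- dplyr::bind_rows(
            picks,
            dplyr::mutate(closest_to_median(improved), role = "improved_median"),
            dplyr::mutate(closest_to_median(degraded), role = "degraded_median")
          )
        }
      }
      picks
    }) |>
    dplyr::ungroup()
  dplyr::select(out, "group", "role", "participant_id", "mae_within",
                "delta_mae")
}
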