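# ggplot2 figures for the standard result displays.

#' Boxplots of participant-average metrics by strategy
#'
#' One panel per metric (participant-average MAE in degrees and Pearson R),
#' boxes per group and strategy; Tukey whiskers at 1.5 x IQR with outliers as
#' open circles, matching [boxplot_stats()].
#'
#' @param records `metric_records` with both strategies.
#' @return A ggplot object.
#' @export
plot_metric_boxes <- function(records) {
  long <- records |>
    dplyr::select("participant_id", "group", "strategy", "mae_avg", "r_avg") |>
    tidyr::pivot_longer(c("mae_avg", "r_avg"), names_to = "metric") |>
    dplyr::mutate(metric = dplyr::recode(.data$metric,
                                         mae_avg = "MAE (deg)",
                                         r_avg = "Pearson R"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                     fill = .data$strategy)) +
    ggplot2::geom_boxplot(outlier.shape = 1, coef = 1.5,
                          position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, fill = "training") +
    ggplot2::theme_minimal()
}

#' Forest plot of mean strategy differences with bootstrap CIs
#'
#' @param object A `paired_comparisons` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot paired_comparisons
#' @export
autoplot.paired_comparisons <- function(object, ...) {
  tbl <- object$table |>
    dplyr::mutate(metric = dplyr::recode(.data$metric, mae = "Delta MAE (deg)",
                                         r = "Delta R"))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$mean_delta, y = .data$group)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lower,
                                         xmax = .data$ci_upper), height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$significant_corrected),
                        size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::labs(x = "cross - within (mean, 95% bootstrap CI)", y = NULL,
                  shape = "significant\n(corrected)") +
    ggplot2::theme_minimal()
}

#' Time-series panel for one participant's test predictions
#'
#' Ground truth against the within- and cross-population ensemble estimates
#' for each joint-side channel, with an absolute-error trace underneath each
#' angle panel.
#'
#' @param truth N x 6 matrix in degrees.
#' @param within,cross N x 6 ensemble prediction matrices (either may be
#'   NULL).
#' @param sample_rate Window-end sampling rate in Hz (window stride permitting,
#'   defaults to one point per stride of 100 ms).
#' @return A ggplot object.
#' @export
plot_participant_timeseries <- function(truth, within = NULL, cross = NULL,
                                        sample_rate = 10) {
  stack <- function(mat, label) {
    if (is.null(mat)) return(NULL)
    tibble::as_tibble(mat) |>
      dplyr::mutate(t = (dplyr::row_number() - 1) / sample_rate,
                    series = label) |>
      tidyr::pivot_longer(dplyr::all_of(ANGLE_CHANNELS),
                          names_to = "channel", values_to = "angle")
  }
  df <- dplyr::bind_rows(stack(truth, "truth"), stack(within, "within"),
                         stack(cross, "cross"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$angle,
                                   colour = .data$series,
                                   linetype = .data$series)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~channel, ncol = 2, scales = "free_y") +
    ggplot2::scale_linetype_manual(values = c(truth = 3, within = 1, cross = 1)) +
    ggplot2::labs(x = "time (s)", y = "angle (deg)", colour = NULL,
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Training and validation loss curves
#'
#' @param runs A `trained_run` or list of them.
#' @return A ggplot object.
#' @export
plot_loss_curves <- function(runs) {
  if (inherits(runs, "trained_run")) runs <- list(runs)
  df <- purrr::imap(runs, function(r, i) {
    dplyr::mutate(r$history, run = sprintf(
      "%s/%s o%d i%d", r$plan$strategy, r$plan$group %||% "all",
      r$plan$outer_fold, r$plan$inner_fold))
  }) |>
    dplyr::bind_rows() |>
    tidyr::pivot_longer(c("train_loss", "val_loss"), names_to = "split") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$run,
                                   linetype = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "Huber loss (standardized)",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}
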