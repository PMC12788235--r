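# Paired comparison of the two training strategies: Wilcoxon signed-rank
# tests, percentile-bootstrap confidence intervals, Bonferroni correction and
# signed effect sizes.

#' Two-sided Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are excluded before ranking; tied absolute differences
#' receive average ranks with the tie-corrected variance. The primary p-value
#' comes from the normal approximation with the standard 0.5 continuity
#' correction (the effect size is built from the same standardized normal
#' deviate z); for `n_effective <= exact_max` an exact enumeration over all
#' sign assignments is reported alongside and agrees with the approximation
#' to within about 0.02 for moderate n.
#'
#' @param diffs Numeric vector of paired differences.
#' @param exact_max Largest `n_effective` for which the exact enumeration is
#'   also computed (default 12).
#' @return List: `p` (normal approximation), `z`, `n_effective`, `statistic`
#'   (W+, the sum of positive ranks), `p_exact` (NA above `exact_max`).
#' @export
wilcoxon_signed_rank <- function(diffs, exact_max = 12L) {
  d <- diffs[!is.na(diffs)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) abort("no informative pairs: all differences are zero.")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) abort("degenerate rank variance; cannot test.")
  dev <- w_pos - mu
  z <- (dev - 0.5 * sign(dev)) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  p_exact <- NA_real_
  if (n <= exact_max) {
    p_exact <- wilcoxon_exact_p(d)
  }
  list(p = p, z = z, n_effective = n, statistic = w_pos, p_exact = p_exact)
}

# exact two-sided p by enumeration of all 2^n sign assignments, with average
# ranks for tied magnitudes: p = min(1, 2 * min(P(W <= w), P(W >= w)))
wilcoxon_exact_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  m <- 2^n
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  tol <- 1e-9
  p_le <- mean(w_all <= w_obs + tol)
  p_ge <- mean(w_all >= w_obs - tol)
  min(1, 2 * min(p_le, p_ge))
}

#' Percentile-bootstrap confidence interval for the mean difference
#'
#' Participants (the exchangeable unit) are resampled with replacement; the
#' statistic is the mean difference and the interval is the empirical
#' `(1 - level)/2` and `1 - (1 - level)/2` percentiles of the bootstrap
#' distribution.
#'
#' @param diffs Numeric vector of paired differences (length >= 2).
#' @param B Number of bootstrap resamples (study setting: 10,000).
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return Named numeric `c(lower, upper)`.
#' @export
bootstrap_ci <- function(diffs, B = 10000L, level = 0.95, seed = 0L) {
  d <- diffs[!is.na(diffs)]
  n <- length(d)
  if (n < 2L) abort("need at least 2 differences for a bootstrap interval.")
  with_seed(derive_seed(seed, "bootstrap", n, B), {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
    means <- colMeans(matrix(d[idx], nrow = n))
    alpha <- (1 - level) / 2
    ci <- unname(quantile(means, c(alpha, 1 - alpha), type = 7))
    c(lower = ci[1], upper = ci[2])
  })
}

#' Bonferroni correction
#'
#' @param p Uncorrected p-value(s) in `[0, 1]`.
#' @param m Number of tests (study setting: 6 = 3 groups x 2 metrics).
#' @return `min(1, m * p)`.
#' @export
bonferroni <- function(p, m = 6L) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  pmin(1, m * p)
}

#' Signed effect size from the Wilcoxon z
#'
#' `r = |z| / sqrt(n_effective)`, with the sign taken from the median of the
#' paired differences (cross minus within). A median of exactly zero with a
#' non-zero z is flagged and yields sign 0.
#'
#' @param z Standardized normal deviate from [wilcoxon_signed_rank()].
#' @param n_effective Number of non-zero pairs.
#' @param diffs The paired differences (for the sign).
#' @return Signed effect size r.
#' @export
effect_size <- function(z, n_effective, diffs) {
  if (n_effective < 1L) abort("`n_effective` must be >= 1.")
  med <- median(diffs[!is.na(diffs) & diffs != 0])
  s <- sign(med)
  if (s == 0 && z != 0) {
    warn("median difference is exactly zero; effect size sign set to 0.")
  }
  s * abs(z) / sqrt(n_effective)
}

#' Compare the two training strategies per group and metric
#'
#' One paired comparison per (group x metric): mean difference with SD,
#' percentile-bootstrap CI, two-sided Wilcoxon signed-rank p, Bonferroni
#' correction across all comparisons, and the signed effect size. Differences
#' are `cross - within`, so negative MAE differences and positive R
#' differences indicate that cross-population training helped.
#'
#' @param records `metric_records` containing both strategies (see
#'   [compute_metrics()]).
#' @param B Bootstrap resamples.
#' @param seed Integer seed for the bootstrap.
#' @param m Number of tests for Bonferroni (default: number of comparisons).
#' @return An object of class `paired_comparisons`; use [tidy()] for the
#'   table.
#' @export
compare_strategies <- function(records, B = 10000L, seed = 0L, m = NULL) {
  deltas <- participant_deltas(records)
  groups <- sort(unique(deltas$group))
  grid <- tidyr::expand_grid(group = groups, metric = c("mae", "r"))
  m <- m %||% nrow(grid)
  rows <- purrr::pmap(grid, function(group, metric) {
    d <- deltas[deltas$group == group, ]
    x <- if (metric == "mae") d$delta_mae else d$delta_r
    w <- wilcoxon_signed_rank(x)
    ci <- bootstrap_ci(x, B = B, seed = derive_seed(seed, group, metric))
    r <- effect_size(w$z, w$n_effective, x)
    tibble::tibble(
      group = group, metric = metric, n = nrow(d),
      mean_delta = mean(x), sd_delta = sd(x),
      ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
      p = w$p, p_exact = w$p_exact, z = w$z, n_effective = w$n_effective,
      effect_r = r
    )
  })
  tbl <- dplyr::bind_rows(rows) |>
    dplyr::mutate(
      p_bonferroni = bonferroni(.data$p, m),
      significant = .data$p < 0.05,
      significant_corrected = .data$p_bonferroni < 0.05
    )
  structure(list(table = tbl, B = B, seed = seed, m = m),
            class = "paired_comparisons")
}

#' @export
print.paired_comparisons <- function(x, ...) {
  cat(sprintf("<paired_comparisons> %d tests, Bonferroni m = %d, B = %d\n",
              nrow(x$table), x$m, x$B))
  print(as.data.frame(dplyr::select(
    x$table, "group", "metric", "n", "mean_delta", "ci_lower", "ci_upper",
    "p", "p_bonferroni", "effect_r"
  )), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Tidy a paired-comparisons object
#'
#' @param x A `paired_comparisons` object.
#' @param ... Unused.
#' @return One row per (group x metric) with the comparison statistics.
#' @method tidy paired_comparisons
#' @export
tidy.paired_comparisons <- function(x, ...) x$table

#' One-row summary of a paired-comparisons object
#'
#' @param x A `paired_comparisons` object.
#' @param ... Unused.
#' @return Tibble: n_tests, n_significant, n_significant_corrected, m, B.
#' @method glance paired_comparisons
#' @export
glance.paired_comparisons <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x$table),
    n_significant = sum(x$table$significant),
    n_significant_corrected = sum(x$table$significant_corrected),
    m = x$m, B = x$B
  )
}
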