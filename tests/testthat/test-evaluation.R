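# Metrics in degrees, table aggregation arithmetic, boxplot statistics and
# representative selection.

test_that("perfect predictions give MAE 0 and R 1; hand case gives 1.0/1.0", {
  prov <- tibble::tibble(participant_id = "A", group = "g")[rep(1, 3), ]
  truth <- matrix(rep(c(0, 10, 20), 6), 3, 6)
  rec <- compute_metrics(truth, truth, prov)
  expect_equal(unname(unlist(rec[paste0("mae_", gaitxpop:::ANGLE_CHANNELS)])),
               rep(0, 6))
  expect_equal(rec$r_avg, 1)

  pred <- truth + 1
  rec2 <- compute_metrics(pred, truth, prov)
  expect_equal(rec2$mae_avg, 1.0)
  expect_equal(rec2$r_avg, 1.0)
})

test_that("constant channels flag R as missing and stay out of averages", {
  prov <- tibble::tibble(participant_id = "A", group = "g")[rep(1, 4), ]
  truth <- matrix(rnorm(24), 4, 6)
  truth[, 2] <- 3                      # constant channel
  pred <- truth + 0.5
  expect_warning(rec <- compute_metrics(pred, truth, prov), "constant")
  expect_true(is.na(rec$r_hipR))
  expect_false(is.na(rec$r_avg))
  expect_equal(rec$mae_avg, 0.5)       # MAE is unaffected
})

test_that("bilateral and participant averages reproduce the printed tables", {
  # young within-population joint MAEs: hip 5.34, knee 4.54, ankle 3.41
  rec <- records_from_values("Y00", "young", "within", 1, 0.9)
  for (j in c("hip", "knee", "ankle")) {
    v <- c(hip = 5.34, knee = 4.54, ankle = 3.41)[[j]]
    rec[[paste0("mae_", j, "L")]] <- v
    rec[[paste0("mae_", j, "R")]] <- v
  }
  rec <- add_bilateral_averages(rec)
  expect_equal(rec$mae_avg, 4.43, tolerance = 5e-3)

  # older within-population joint Rs: 0.961, 0.942, 0.894 -> average 0.932
  rec2 <- records_from_values("O00", "older", "within", 1, 0)
  for (j in c("hip", "knee", "ankle")) {
    v <- c(hip = 0.961, knee = 0.942, ankle = 0.894)[[j]]
    rec2[[paste0("r_", j, "L")]] <- v
    rec2[[paste0("r_", j, "R")]] <- v
  }
  rec2 <- add_bilateral_averages(rec2)
  expect_equal(rec2$r_avg, 0.932, tolerance = 5e-4)

  # participant average equals the mean of the three bilateral values and of
  # the six joint-side values (equal-weight mean associativity)
  rec3 <- records_from_values("X", "g", "within", 2, 0.5)
  rec3[paste0("mae_", gaitxpop:::ANGLE_CHANNELS)] <-
    as.list(c(1, 2, 3, 4, 5, 6))
  rec3 <- add_bilateral_averages(rec3)
  expect_equal(rec3$mae_avg, mean(1:6))
  expect_equal(rec3$mae_avg, mean(c(rec3$mae_hip, rec3$mae_knee,
                                    rec3$mae_ankle)))
})

test_that("group delta columns reproduce the older-knee difference", {
  mk <- function(strategy, knee) {
    r <- records_from_values("O01", "older", strategy, 1, 0.9)
    r$mae_kneeL <- knee
    r$mae_kneeR <- knee
    add_bilateral_averages(r)
  }
  recs <- dplyr::bind_rows(mk("within", 5.50), mk("cross", 5.03))
  agg <- aggregate_group(recs)
  knee <- agg[agg$metric == "mae" & agg$joint == "knee", ]
  expect_equal(knee$delta, -0.47, tolerance = 1e-9)
  # single participant: group mean equals the participant
  expect_equal(knee$within, 5.50)
})

test_that("participant deltas reproduce the printed per-participant rows", {
  recs <- dplyr::bind_rows(
    records_from_values(c("P11", "P12"), "preop", "within",
                        mae = c(8.03, 6.25), r = c(0.795, 0.821)),
    records_from_values(c("P11", "P12"), "preop", "cross",
                        mae = c(6.48, 7.31), r = c(0.857, 0.628))
  )
  d <- participant_deltas(recs)
  expect_equal(d$delta_mae[d$participant_id == "P11"], -1.55, tolerance = 1e-9)
  expect_equal(d$delta_r[d$participant_id == "P12"], -0.193, tolerance = 1e-9)
  # identical strategies -> all deltas zero
  same <- dplyr::bind_rows(
    records_from_values("A", "g", "within", 3, 0.8),
    records_from_values("A", "g", "cross", 3, 0.8)
  )
  d0 <- participant_deltas(same)
  expect_equal(d0$delta_mae, 0)
  expect_equal(d0$delta_r, 0)
})

test_that("metrics are invariant to window ordering", {
  prov <- tibble::tibble(participant_id = rep(c("A", "B"), each = 10),
                         group = "g")
  set.seed(21)
  truth <- matrix(rnorm(120), 20, 6)
  pred <- truth + matrix(rnorm(120, 0, 0.3), 20, 6)
  r1 <- compute_metrics(pred, truth, prov)
  perm <- sample(20)
  r2 <- compute_metrics(pred[perm, ], truth[perm, ], prov[perm, ])
  expect_equal(dplyr::arrange(r1, .data$participant_id),
               dplyr::arrange(r2, .data$participant_id))
})

test_that("boxplot statistics follow the Tukey 1.5 IQR rule", {
  b <- boxplot_stats(c(1, 2, 3, 4, 100))
  expect_equal(b$outliers, 100)
  expect_equal(b$whisker_hi, 4)
  expect_equal(b$q1, 2)
  expect_equal(b$q3, 4)

  b2 <- boxplot_stats(rep(7, 5))
  expect_equal(b2$iqr, 0)
  expect_length(b2$outliers, 0)

  expect_equal(boxplot_stats(1:8)$median, 4.5)
  expect_error(boxplot_stats(numeric(0)), "no values")
})

test_that("representatives follow best / median / worst and subgroup rules", {
  deltas <- tibble::tibble(
    participant_id = c("A", "B", "C", "D", "E"),
    group = "g",
    mae_within = c(3, 4, 5, 6, 7), mae_cross = c(2, 5, 4.8, 5.5, 8),
    delta_mae = c(-1, 1, -0.2, -0.5, 1),
    r_within = 0.9, r_cross = 0.9, delta_r = 0
  )
  reps <- select_representatives(deltas)
  expect_equal(reps$participant_id[reps$role == "best"], "A")
  expect_equal(reps$participant_id[reps$role == "worst"],
               reps$participant_id[reps$role == "worst"][1])
  # median within-MAE is 5 -> C
  expect_equal(reps$participant_id[reps$role == "median"], "C")

  # subgroup split: improved {A, C, D}, degraded {B, E}
  reps2 <- select_representatives(deltas, split_heterogeneous = TRUE)
  expect_equal(reps2$participant_id[reps2$role == "improved_median"], "C")
  expect_true(reps2$participant_id[reps2$role == "degraded_median"] %in%
                c("B", "E"))

  # a single-participant group is best, worst and median at once
  one <- select_representatives(deltas[1, ])
  expect_equal(unique(one$participant_id), "A")
  expect_setequal(one$role, c("best", "median", "worst"))

  # distance tie to the median breaks to the lowest participant id
  tie <- tibble::tibble(participant_id = c("B", "A", "C"), group = "g",
                        mae_within = c(3, 5, 4), mae_cross = 4,
                        delta_mae = c(1, -1, 0), r_within = 0.9,
                        r_cross = 0.9, delta_r = 0)
  reps3 <- select_representatives(tie)
  expect_equal(reps3$participant_id[reps3$role == "median"], "C")
  tie2 <- tie
  tie2$mae_within <- c(3, 5, 99)       # median 5; |3-5| = |5-5|? no: test equal distance
  tie2$mae_within <- c(4, 6, 5)        # median 5 -> C exact
  reps4 <- select_representatives(tie2)
  expect_equal(reps4$participant_id[reps4$role == "median"], "C")
})
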