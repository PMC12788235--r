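# Fold assignment, run enumeration, participant balancing and the training
# loop (both engines).

manifest_of <- function(ns) {
  dplyr::bind_rows(purrr::imap(ns, function(n, g) {
    tibble::tibble(participant_id = sprintf("%s%02d", toupper(substr(g, 1, 1)),
                                            seq_len(n)),
                   group = g)
  }))
}

test_that("fold assignment is balanced per group and reproducible", {
  man <- manifest_of(c(young = 17, older = 20, preop = 14))
  a <- assign_folds(man, k = 5, seed = 3)
  expect_equal(nrow(a), 51)
  sizes <- a |> dplyr::count(.data$group, .data$fold)
  expect_equal(sort(sizes$n[sizes$group == "older"]), rep(4, 5))
  expect_equal(sort(sizes$n[sizes$group == "preop"]), c(2, 3, 3, 3, 3))
  expect_equal(sort(sizes$n[sizes$group == "young"]), c(3, 3, 3, 4, 4))
  expect_identical(a, assign_folds(man, k = 5, seed = 3))
  expect_false(identical(a$fold, assign_folds(man, k = 5, seed = 4)$fold))
  expect_error(assign_folds(manifest_of(c(tiny = 3)), k = 5), "at least 5")
})

test_that("run enumeration yields 5x4 runs per group (within) and 20 pooled (cross)", {
  man <- manifest_of(c(young = 6, older = 5, preop = 5))
  a <- assign_folds(man, k = 5, seed = 1)
  w1 <- enumerate_runs(a, "within", groups = "young")
  expect_equal(nrow(w1), 20)
  w3 <- enumerate_runs(a, "within")
  expect_equal(nrow(w3), 60)
  cr <- enumerate_runs(a, "cross")
  expect_equal(nrow(cr), 20)
  for (i in seq_len(nrow(cr))) {
    test_groups <- a$group[a$participant_id %in% cr$test[[i]]]
    expect_setequal(unique(test_groups), c("young", "older", "preop"))
  }
})

test_that("test participants never leak into training or validation", {
  man <- manifest_of(c(young = 6, older = 5, preop = 5))
  a <- assign_folds(man, k = 5, seed = 2)
  all_runs <- dplyr::bind_rows(enumerate_runs(a, "within"),
                               enumerate_runs(a, "cross"))
  for (i in seq_len(nrow(all_runs))) {
    expect_length(intersect(all_runs$test[[i]],
                            union(all_runs$train[[i]], all_runs$val[[i]])), 0)
    expect_length(intersect(all_runs$train[[i]], all_runs$val[[i]]), 0)
  }
})

test_that("sampler weights are inverse window counts with balanced expectation", {
  prov <- tibble::tibble(
    participant_id = c(rep("A", 100), rep("B", 300)),
    group = "g", segment = 1L, end_frame = 1L
  )
  ds <- structure(list(inputs = array(0, c(6, 1, 400)),
                       targets = matrix(0, 400, 6), provenance = prov,
                       config = window_config(1, 1)),
                  class = "window_dataset")
  sw <- compute_sampler_weights(ds, c("A", "B"))
  expect_equal(sw$weight[sw$participant_id == "A"], rep(1 / 100, 100))
  expect_equal(sw$weight[sw$participant_id == "B"], rep(1 / 300, 300))
  # expected share per participant is uniform: 1 / n_participants
  share_A <- sum(sw$weight[sw$participant_id == "A"]) / sum(sw$weight)
  expect_equal(share_A, 0.5)
  expect_equal(attr(sw, "draws_per_epoch"), 400L)

  one <- compute_sampler_weights(ds, "A")
  expect_equal(unique(one$weight), 1 / 100)
  expect_warning(compute_sampler_weights(ds, c("A", "B", "Z")), "Z")
})

test_that("training reduces the loss and is exactly reproducible", {
  ds <- tiny_dataset(n = 2, duration = 8, noise = 0.01)
  ids <- unique(ds$provenance$participant_id)
  plan <- list(strategy = "within", group = "young", outer_fold = 1L,
               inner_fold = 2L, train = ids[1], val = character(0),
               test = ids[2])
  cfg <- train_config(epochs = 3, batch_size = 16, width_multiplier = 0.1,
                      max_windows_per_participant = 60, validate = FALSE,
                      seed = 5)
  r1 <- train_run(plan, cfg, ds)
  expect_lt(dplyr::last(r1$history$train_loss), r1$history$train_loss[1])
  r2 <- train_run(plan, cfg, ds)
  expect_identical(r1$history, r2$history)
  expect_identical(gaitxpop:::collect_params(r1$est["head"]),
                   gaitxpop:::collect_params(r2$est["head"]))
})

test_that("compiled and reference training engines agree step for step", {
  ds <- tiny_dataset(n = 2, duration = 6, noise = 0.05)
  ids <- unique(ds$provenance$participant_id)
  plan <- list(strategy = "within", group = "young", outer_fold = 1L,
               inner_fold = 2L, train = ids, val = character(0),
               test = character(0))
  mk <- function(engine) train_run(plan, train_config(
    epochs = 2, batch_size = 16, width_multiplier = 0.05,
    max_windows_per_participant = 30, validate = FALSE, seed = 7,
    engine = engine), ds)
  rc <- mk("cpp")
  rr <- mk("r")
  expect_equal(rc$history$train_loss, rr$history$train_loss, tolerance = 1e-10)
  expect_equal(gaitxpop:::collect_params(rc$est["head"]),
               gaitxpop:::collect_params(rr$est["head"]), tolerance = 1e-8)
})

test_that("ensemble prediction is the mean of the inner models, in degrees", {
  ds <- tiny_dataset(n = 2, duration = 6)
  ids <- unique(ds$provenance$participant_id)
  spec <- model_spec(width_multiplier = 0.05)
  # four stub models predicting the constants 1, 2, 3, 4 degrees
  st <- fit_standardizer(ds, ids)
  runs <- lapply(1:4, function(k) {
    est <- build_model(spec, seed = k)
    est$head$out_layer$W[] <- 0
    est$head$out_layer$b <- (k - st$target_mean) / st$target_sd
    structure(list(est = est, standardizer = st,
                   history = tibble::tibble(),
                   plan = list(strategy = "within", group = "young",
                               outer_fold = 1L, inner_fold = k,
                               test = ids[1]),
                   seed = k),
              class = "trained_run")
  })
  pt <- predict_test(runs, ds)
  expect_equal(unname(pt$ensemble[1, ]), rep(2.5, 6), tolerance = 1e-9)
  expect_equal(pt$per_model[[3]][5, ], rep(3, 6), tolerance = 1e-9,
               ignore_attr = TRUE)
  # four identical models: ensemble equals any single model
  pt2 <- predict_test(runs[c(1, 1, 1, 1)], ds)
  expect_equal(pt2$ensemble, pt2$per_model[[1]], ignore_attr = TRUE)
  expect_error(predict_test(list(), ds), "no trained")
})

test_that("ensemble MAE does not exceed the worst inner model's MAE", {
  ds <- tiny_dataset(n = 3, duration = 8, noise = 0.02)
  ids <- unique(ds$provenance$participant_id)
  cfg <- train_config(epochs = 2, batch_size = 16, width_multiplier = 0.1,
                      max_windows_per_participant = 50, validate = FALSE,
                      seed = 2)
  runs <- lapply(2:3, function(j) {
    train_run(list(strategy = "within", group = "young", outer_fold = 1L,
                   inner_fold = j, train = ids[setdiff(2:3, j)], val = ids[j],
                   test = ids[1]), cfg, ds)
  })
  pt <- predict_test(runs, ds)
  mae_of <- function(p) mean(abs(p - pt$truth))
  expect_lte(mae_of(pt$ensemble), max(vapply(pt$per_model, mae_of, numeric(1))))
})

test_that("a trained network matches or beats a ridge readout on easy data", {
  prof <- learnability_profile()
  specs <- sample_population(prof, 1)
  recs <- lapply(1:5, function(i) generate_recording(specs[i, ], 1))
  ds <- make_windows(recs, window_config(200, 10))
  ids <- unique(ds$provenance$participant_id)
  plan <- list(strategy = "within", group = "young", outer_fold = 1L,
               inner_fold = 2L, train = ids[3:5], val = character(0),
               test = ids[1])
  cfg <- scaled_train_config(epochs = 25, seed = 1)
  run <- train_run(plan, cfg, ds)
  test_ds <- subset_windows(ds, participants = plan$test)
  Xs <- apply_standardizer(test_ds$inputs, run$standardizer, "inputs")
  pred <- invert_standardizer(predict_windows(run$est, Xs), run$standardizer)
  net_mae <- mean(abs(pred - test_ds$targets))
  # independent linear-readout oracle: closed-form ridge (lambda = 1) from the
  # flattened standardized windows to the standardized targets
  tr_idx <- gaitxpop:::cap_windows(ds$provenance, plan$train,
                                   cfg$max_windows_per_participant)
  tr <- subset_windows(ds, tr_idx)
  Xtr <- t(matrix(apply_standardizer(tr$inputs, run$standardizer, "inputs"), 1200))
  Ytr <- apply_standardizer(tr$targets, run$standardizer, "targets")
  W <- solve(crossprod(Xtr) + diag(1, 1200), crossprod(Xtr, Ytr))
  pred_ridge <- invert_standardizer(t(matrix(Xs, 1200)) %*% W, run$standardizer)
  ridge_mae <- mean(abs(pred_ridge - test_ds$targets))
  expect_lte(net_mae, ridge_mae)
})
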