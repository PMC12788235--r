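# Nested participant-level cross-validation under the two training strategies.
#
# Outer loop: each of k folds serves once as the test set. Inner loop: the
# remaining folds are split k-1 ways, each serving once as validation with the
# rest as training. Within-population runs use one group's participants only;
# cross-population runs pool the matching folds of every group. Test
# participants never appear in training or validation of the same run.

#' Assign participants to cross-validation folds
#'
#' Balanced random partition per group (fold sizes differ by at most one
#' within each group). The assignment is a pure function of `(manifest, k,
#' seed)` and is intended to be computed once and reused verbatim by both
#' strategies so results stay comparable.
#'
#' @param manifest Data frame with `participant_id` and `group` columns.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return A tibble of class `fold_assignment`: participant_id, group, fold.
#' @export
assign_folds <- function(manifest, k = 5L, seed = 0L) {
  stopifnot(all(c("participant_id", "group") %in% names(manifest)))
  k <- as.integer(k)
  out <- manifest |>
    tibble::as_tibble() |>
    dplyr::distinct(.data$participant_id, .data$group) |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      if (n < k) {
        abort(sprintf("group '%s' has %d participants; at least %d required for %d folds.",
                      key$group, n, k, k))
      }
      with_seed(derive_seed(seed, "folds", key$group), {
        counts <- n %/% k + (seq_len(k) <= n %% k)
        counts <- sample(counts)              # which folds carry the extras
        df$fold <- sample(rep(seq_len(k), counts))
      })
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$group, .data$participant_id)
  class(out) <- c("fold_assignment", class(out))
  out
}

participants_in <- function(assignment, folds, groups = NULL) {
  x <- assignment[assignment$fold %in% folds, ]
  if (!is.null(groups)) x <- x[x$group %in% groups, ]
  sort(x$participant_id)
}

#' Enumerate nested cross-validation runs
#'
#' For the within-population strategy each group yields `k * (k - 1)` runs
#' (outer test fold x inner validation fold); the cross-population strategy
#' yields `k * (k - 1)` runs in total, each pooling the matching folds of all
#' groups for training and validation and testing on the pooled outer fold.
#'
#' @param assignment A [assign_folds()] result.
#' @param strategy `"within"` or `"cross"`.
#' @param groups Groups to enumerate (default: all in the assignment).
#' @return A tibble of run plans with list-columns `train`, `val`, `test`
#'   holding participant-id vectors.
#' @export
enumerate_runs <- function(assignment, strategy = c("within", "cross"),
                           groups = NULL) {
  strategy <- match.arg(strategy)
  ks <- sort(unique(assignment$fold))
  if (is.null(groups)) groups <- sort(unique(assignment$group))
  grid <- tidyr::expand_grid(outer_fold = ks, inner_fold = ks) |>
    dplyr::filter(.data$inner_fold != .data$outer_fold)
  plans <- if (strategy == "within") {
    tidyr::expand_grid(group = groups, grid) |>
      dplyr::mutate(
        strategy = "within",
        train = purrr::pmap(list(.data$group, .data$outer_fold, .data$inner_fold),
                            function(g, ko, ki)
                              participants_in(assignment,
                                              setdiff(ks, c(ko, ki)), g)),
        val = purrr::map2(.data$group, .data$inner_fold,
                          function(g, ki) participants_in(assignment, ki, g)),
        test = purrr::map2(.data$group, .data$outer_fold,
                           function(g, ko) participants_in(assignment, ko, g))
      )
  } else {
    grid |>
      dplyr::mutate(
        strategy = "cross",
        group = NA_character_,
        train = purrr::map2(.data$outer_fold, .data$inner_fold,
                            function(ko, ki)
                              participants_in(assignment, setdiff(ks, c(ko, ki)),
                                              groups)),
        val = purrr::map(.data$inner_fold,
                         function(ki) participants_in(assignment, ki, groups)),
        test = purrr::map(.data$outer_fold,
                          function(ko) participants_in(assignment, ko, groups))
      )
  }
  dplyr::select(plans, "strategy", "group", "outer_fold", "inner_fold",
                "train", "val", "test")
}

#' Participant-balancing sampler weights
#'
#' Every training window is weighted by the inverse of its participant's
#' window count, so each epoch's with-replacement draw represents every
#' training participant equally in expectation regardless of walking
#' duration. Applied to training data only; validation and test data are
#' processed sequentially.
#'
#' @param ds A `window_dataset`.
#' @param training_ids Participant ids forming the training set.
#' @return A tibble (window index `idx`, `participant_id`, `weight`); the
#'   per-epoch draw count (number of training windows) is attached as
#'   `attr(, "draws_per_epoch")`.
#' @export
compute_sampler_weights <- function(ds, training_ids) {
  counts <- ds$provenance |>
    dplyr::mutate(idx = dplyr::row_number()) |>
    dplyr::filter(.data$participant_id %in% training_ids) |>
    dplyr::add_count(.data$participant_id, name = "n_windows")
  missing <- setdiff(training_ids, counts$participant_id)
  if (length(missing)) {
    warn(sprintf("training participant(s) without windows excluded: %s",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(counts) == 0L) abort("no training windows available.")
  out <- tibble::tibble(idx = counts$idx,
                        participant_id = counts$participant_id,
                        weight = 1 / counts$n_windows)
  attr(out, "draws_per_epoch") <- nrow(out)
  out
}

#' Training configuration
#'
#' Published settings: 100 epochs, batch size 128, Adam with learning rate
#' 0.001 (conventional moment coefficients) and Huber loss on standardized
#' targets. `width_multiplier` and `max_windows_per_participant` support
#' desk-scale profiles; there is no early stopping or schedule — the
#' final-epoch weights are used and validation loss is monitoring only.
#'
#' @param epochs,batch_size,learning_rate,huber_delta Optimization settings.
#' @param width_multiplier Passed to [model_spec()].
#' @param max_windows_per_participant Cap on training windows per participant
#'   (evenly spaced thinning; `Inf` = use all).
#' @param validate Compute per-epoch validation loss.
#' @param seed Integer seed; every run derives its own child seed from it.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 128L,
                         learning_rate = 0.001, huber_delta = 1,
                         width_multiplier = 1,
                         max_windows_per_participant = Inf,
                         validate = TRUE, seed = 0L,
                         engine = c("cpp", "r")) {
  stopifnot_scalar_number(epochs, "epochs", min = 1)
  stopifnot_scalar_number(batch_size, "batch_size", min = 1)
  stopifnot_scalar_number(learning_rate, "learning_rate", min = 0, strict_min = TRUE)
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, huber_delta = huber_delta,
         width_multiplier = width_multiplier,
         max_windows_per_participant = max_windows_per_participant,
         validate = validate, seed = as.integer(seed),
         engine = match.arg(engine)),
    class = "train_config"
  )
}

#' Desk-scale training profile
#'
#' A reduced profile for CPU experiments and continuous testing: width
#' multiplier 0.25, 5 epochs, at most 200 windows per participant (evenly
#' thinned), batch size 16, no per-epoch validation pass. The learning rate
#' and loss are unchanged from the published settings; the smaller batch keeps
#' the number of optimizer updates meaningful within 5 epochs at desk-scale
#' window counts.
#'
#' @param ... Overrides passed to [train_config()].
#' @export
scaled_train_config <- function(...) {
  defaults <- list(epochs = 5L, width_multiplier = 0.25, batch_size = 16L,
                   max_windows_per_participant = 200L, validate = FALSE)
  args <- utils::modifyList(defaults, list(...))
  do.call(train_config, args)
}

# evenly spaced thinning of each participant's window indices
cap_windows <- function(prov, ids, cap) {
  idx <- which(prov$participant_id %in% ids)
  if (!is.finite(cap)) return(idx)
  split(idx, prov$participant_id[idx]) |>
    purrr::map(function(ii) {
      if (length(ii) <= cap) ii else ii[round(seq(1, length(ii), length.out = cap))]
    }) |>
    unlist(use.names = FALSE) |>
    sort()
}

#' Train one nested cross-validation run
#'
#' Fits the z-score standardizer on the run's training participants only,
#' standardizes inputs and targets, builds a fresh network seeded from the
#' configuration and the run coordinates, and minimizes the Huber loss with
#' Adam under participant-balanced with-replacement sampling. The final-epoch
#' weights are returned together with the per-epoch loss history.
#'
#' @param plan One row of an [enumerate_runs()] tibble.
#' @param cfg A [train_config()].
#' @param ds The full `window_dataset`.
#' @return List of class `trained_run`: `est`, `standardizer`, `history`
#'   (tibble epoch/train_loss/val_loss), `plan`, `seed`.
#' @export
train_run <- function(plan, cfg, ds) {
  if (inherits(plan, "data.frame")) {
    stopifnot(nrow(plan) == 1L)
    plan <- as.list(plan)
    for (f in c("train", "val", "test")) plan[[f]] <- plan[[f]][[1]]
  }
  run_seed <- derive_seed(cfg$seed, "run", plan$strategy,
                          plan$group %||% "all", plan$outer_fold,
                          plan$inner_fold)
  train_idx <- cap_windows(ds$provenance, plan$train,
                           cfg$max_windows_per_participant)
  if (length(train_idx) == 0L) abort("run has no training windows.")
  train_ds <- subset_windows(ds, train_idx)
  st <- fit_standardizer(train_ds, plan$train)
  sw <- compute_sampler_weights(train_ds, plan$train)
  X <- apply_standardizer(train_ds$inputs, st, "inputs")
  Y <- t(apply_standardizer(train_ds$targets, st, "targets"))  # (6, N)
  has_val <- isTRUE(cfg$validate) && length(plan$val) > 0L
  if (has_val) {
    val_ds <- subset_windows(ds, participants = plan$val)
    Xv <- apply_standardizer(val_ds$inputs, st, "inputs")
    Yv <- t(apply_standardizer(val_ds$targets, st, "targets"))
  }
  spec <- model_spec(input_len = ds$config$window_len,
                     width_multiplier = cfg$width_multiplier)
  est <- build_model(spec, seed = run_seed)
  core <- est[c("stem", "stages", "head")]
  params <- collect_params(core)
  buffers <- collect_buffers(core)
  opt <- adam_init(params)
  n_train <- dim(X)[3]
  n_draws <- sum(spec$head_widths)        # dropout draws per window
  use_cpp <- identical(cfg$engine, "cpp")
  history <- vector("list", cfg$epochs)
  with_seed(derive_seed(run_seed, "sgd"), {
    for (epoch in seq_len(cfg$epochs)) {
      order_idx <- sample.int(n_train, n_train, replace = TRUE,
                              prob = sw$weight)
      losses <- c()
      at <- 1L
      while (at <= n_train) {
        bi <- order_idx[at:min(n_train, at + cfg$batch_size - 1L)]
        Xb <- X[, , bi, drop = FALSE]
        Yb <- Y[, bi, drop = FALSE]
        if (use_cpp) {
          draws <- if (spec$dropout > 0) runif(n_draws * length(bi)) else numeric(0)
          res <- cpp_train_batch(params, buffers, Xb, Yb, unclass(spec),
                                 cfg$huber_delta, draws)
          loss <- res$loss
          grads <- res$grads
          buffers <- res$buffers
        } else {
          fw <- resnet_forward(est, Xb, training = TRUE)
          est <- fw$est
          hl <- huber_loss(fw$out, Yb, cfg$huber_delta)
          loss <- hl$loss
          bw <- resnet_backward(est, fw$cache, hl$grad)
          grads <- collect_params(bw$grads)
        }
        if (!is.finite(loss)) {
          abort(sprintf("non-finite training loss at epoch %d; aborting run.",
                        epoch))
        }
        step <- adam_step(params, grads, opt, lr = cfg$learning_rate)
        params <- step$params
        opt <- step$state
        if (!use_cpp) {
          core <- inject_params(est[c("stem", "stages", "head")], params)
          est$stem <- core$stem; est$stages <- core$stages; est$head <- core$head
        }
        losses <- c(losses, loss)
        at <- at + cfg$batch_size
      }
      if (use_cpp) {
        core <- inject_params(est[c("stem", "stages", "head")], params)
        est$stem <- core$stem; est$stages <- core$stages; est$head <- core$head
        core <- inject_buffers(est[c("stem", "stages", "head")], buffers)
        est$stem <- core$stem; est$stages <- core$stages; est$head <- core$head
      }
      val_loss <- NA_real_
      if (has_val) {
        pv <- t(predict_windows(est, Xv, engine = cfg$engine))
        val_loss <- huber_loss(pv, Yv, cfg$huber_delta)$loss
      }
      history[[epoch]] <- tibble::tibble(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_loss = val_loss)
    }
  })
  structure(
    list(est = est, standardizer = st, history = dplyr::bind_rows(history),
         plan = plan, seed = run_seed),
    class = "trained_run"
  )
}

#' @export
print.trained_run <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<trained_run %s/%s outer %d inner %d> final train loss %.4f, val loss %s\n",
    x$plan$strategy, x$plan$group %||% "all", x$plan$outer_fold,
    x$plan$inner_fold, h$train_loss,
    ifelse(is.na(h$val_loss), "-", sprintf("%.4f", h$val_loss))
  ))
  invisible(x)
}

#' Ensemble prediction on an outer test fold
#'
#' Each of the four inner-fold models predicts the test windows after
#' standardizing them with its *own* training standardizer, predictions are
#' inverted back to degrees, and the ensemble is their arithmetic mean.
#' Per-model predictions are retained so metrics can also be computed per
#' inner model.
#'
#' @param runs List of `trained_run` objects sharing one outer fold.
#' @param ds The full `window_dataset`.
#' @return List: `ensemble` (N x 6 matrix, degrees), `per_model` (list of such
#'   matrices), `truth` (N x 6, degrees), `provenance` (tibble).
#' @export
predict_test <- function(runs, ds) {
  if (length(runs) == 0L) abort("no trained inner-fold models supplied.")
  outer <- unique(vapply(runs, function(r) r$plan$outer_fold, numeric(1)))
  if (length(outer) != 1L) abort("runs must share one outer test fold.")
  test_ids <- runs[[1]]$plan$test
  test_ds <- subset_windows(ds, participants = test_ids)
  per_model <- purrr::map(runs, function(r) {
    Xs <- apply_standardizer(test_ds$inputs, r$standardizer, "inputs")
    pred_std <- predict_windows(r$est, Xs)
    invert_standardizer(pred_std, r$standardizer)
  })
  ensemble <- Reduce(`+`, per_model) / length(per_model)
  colnames(ensemble) <- ANGLE_CHANNELS
  list(ensemble = ensemble, per_model = per_model,
       truth = test_ds$targets, provenance = test_ds$provenance)
}

#' Train all inner runs of one outer fold and predict its test set
#'
#' Convenience wrapper: selects the runs of `strategy` (and `group`, for the
#' within strategy) with the given outer fold, trains the inner-fold models,
#' and returns their ensemble test prediction.
#'
#' @param assignment A [assign_folds()] result.
#' @param strategy `"within"` or `"cross"`.
#' @param cfg A [train_config()].
#' @param ds The full `window_dataset`.
#' @param outer_fold Outer test fold index.
#' @param group Group under test (within strategy only).
#' @return List as [predict_test()], plus `runs`.
#' @export
train_outer_fold <- function(assignment, strategy, cfg, ds, outer_fold,
                             group = NULL) {
  plans <- enumerate_runs(assignment, strategy,
                          groups = if (strategy == "within") group else NULL)
  plans <- plans[plans$outer_fold == outer_fold, ]
  if (nrow(plans) == 0L) abort("no runs for the requested outer fold.")
  runs <- purrr::map(seq_len(nrow(plans)),
                     function(i) train_run(plans[i, ], cfg, ds))
  out <- predict_test(runs, ds)
  out$runs <- runs
  out
}
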