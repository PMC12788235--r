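# Architecture contracts: parameter counts against an independent closed-form
# oracle, temporal shapes, and forward-pass determinism.

# closed-form parameter sum: bias-free convs, BN affine pairs, 1x1 conv + BN
# on shape-changing skips, biased linears
closed_form_params <- function(spec) {
  stem <- spec$stem$channels
  n <- spec$in_channels * stem * spec$stem$kernel + 2 * stem
  in_ch <- stem
  for (s in seq_along(spec$stage_channels)) {
    out <- spec$stage_channels[s]
    for (b in seq_len(spec$blocks_per_stage)) {
      stride <- if (b == 1) spec$stage_strides[s] else 1L
      n <- n + in_ch * out * 3 + 2 * out        # conv1 + bn1
      n <- n + out * out * 3 + 2 * out          # conv2 + bn2
      if (stride != 1L || in_ch != out) {
        n <- n + in_ch * out + 2 * out          # downsample conv + bn
      }
      in_ch <- out
    }
  }
  widths <- c(in_ch, spec$head_widths, spec$out_dim)
  for (i in seq_len(length(widths) - 1)) {
    n <- n + widths[i] * widths[i + 1] + widths[i + 1]
  }
  n
}

test_that("the published-scale network has exactly 4,019,014 parameters", {
  est <- build_model(model_spec(), seed = 0)
  expect_identical(count_parameters(est), 4019014L)
  expect_equal(model_size_mb(count_parameters(est)), 15.33, tolerance = 1e-3)
})

test_that("head and stem sub-counts match hand arithmetic", {
  est <- build_model(model_spec(), seed = 0)
  head_n <- gaitxpop:::n_params(est["head"])
  expect_identical(head_n, 131328L + 32896L + 8256L + 390L)  # 172,870
  stem_conv_n <- length(est$stem$conv$W)
  expect_identical(stem_conv_n, 6L * 64L * 7L)               # 2,688
})

test_that("built models match the closed-form count over a spec grid", {
  for (w in c(0.05, 0.1, 0.25, 0.5)) {
    for (out_dim in c(1, 6)) {
      spec <- model_spec(in_channels = 6, input_len = 200, out_dim = out_dim,
                         width_multiplier = w)
      est <- build_model(spec, seed = 3)
      expect_identical(count_parameters(est), as.integer(closed_form_params(spec)),
                       info = sprintf("w=%g out=%d", w, out_dim))
    }
  }
})

test_that("temporal lengths reproduce the published cascade 200->13", {
  spec <- model_spec()
  expect_equal(feature_lengths(spec), c(200, 100, 100, 50, 25, 13))
  est <- build_model(spec, seed = 0)
  expect_equal(probe_feature_lengths(est), c(200, 100, 100, 50, 25, 13))
  # k3/s2/pad1 length recurrence: floor((L - 1) / 2) + 1
  for (L in c(7, 25, 100, 131)) {
    expect_equal(gaitxpop:::conv_out_len(L, 3L, 2L, 1L), floor((L - 1) / 2) + 1)
  }
  expect_error(model_spec(input_len = 0), "too short")
})

test_that("scaled specs probe the same lengths as the closed form", {
  spec <- model_spec(width_multiplier = 0.25, input_len = 120)
  est <- build_model(spec, seed = 1)
  expect_equal(probe_feature_lengths(est), feature_lengths(spec))
})

test_that("forward pass has the contracted shape and is deterministic in eval", {
  spec <- model_spec(width_multiplier = 0.1)
  est <- build_model(spec, seed = 5)
  X <- array(rnorm(6 * 200 * 2), c(6, 200, 2))
  p1 <- predict_windows(est, X)
  expect_equal(dim(p1), c(2, 6))
  expect_true(all(is.finite(p1)))
  expect_identical(p1, predict_windows(est, X))
  # single window without explicit batch dimension
  expect_equal(dim(predict_windows(est, X[, , 1])), c(1, 6))
  expect_error(predict_windows(est, array(0, c(5, 200, 1))), "input must be")
})

test_that("dropout makes training-mode forwards stochastic, eval-mode not", {
  spec <- model_spec(width_multiplier = 0.1, dropout = 0.5)
  est <- build_model(spec, seed = 6)
  X <- array(rnorm(6 * 200 * 2), c(6, 200, 2))
  set.seed(1)
  t1 <- gaitxpop:::resnet_forward(est, X, training = TRUE)$out
  t2 <- gaitxpop:::resnet_forward(est, X, training = TRUE)$out
  expect_false(identical(t1, t2))
  e1 <- gaitxpop:::resnet_forward(est, X, training = FALSE)$out
  e2 <- gaitxpop:::resnet_forward(est, X, training = FALSE)$out
  expect_identical(e1, e2)
})

test_that("weight initialization is a pure function of the seed", {
  a <- build_model(model_spec(width_multiplier = 0.1), seed = 42)
  b <- build_model(model_spec(width_multiplier = 0.1), seed = 42)
  c <- build_model(model_spec(width_multiplier = 0.1), seed = 43)
  expect_identical(gaitxpop:::collect_params(a["head"]),
                   gaitxpop:::collect_params(b["head"]))
  expect_false(identical(gaitxpop:::collect_params(a["head"]),
                         gaitxpop:::collect_params(c["head"])))
})
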