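# Gradient checks for the network engine: analytic backward passes against
# central finite differences. These pin the correctness of every layer
# (convolution, batch norm, GELU, max pool, global pooling, linears, dropout
# scaling) through a tiny end-to-end model.

nn <- function(name) get(name, envir = asNamespace("gaitxpop"))

tiny_est <- function(seed = 1) {
  spec <- model_spec(in_channels = 2, input_len = 20, out_dim = 3,
                     width_multiplier = 0.05, dropout = 0)
  build_model(spec, seed)
}

# loss of the tiny model as a function of its flattened parameters
make_loss_fn <- function(est, X, Y, training = TRUE) {
  core_names <- c("stem", "stages", "head")
  function(params) {
    core <- nn("inject_params")(est[core_names], params)
    est$stem <- core$stem; est$stages <- core$stages; est$head <- core$head
    fw <- nn("resnet_forward")(est, X, training = training)
    huber_loss(fw$out, Y)$loss
  }
}

test_that("analytic parameter gradients match finite differences", {
  est <- tiny_est()
  set.seed(7)
  X <- array(rnorm(2 * 20 * 3), c(2, 20, 3))
  Y <- matrix(rnorm(3 * 3), 3, 3)
  fw <- nn("resnet_forward")(est, X, training = TRUE)
  hl <- huber_loss(fw$out, Y)
  bw <- nn("resnet_backward")(est, fw$cache, hl$grad)
  analytic <- nn("collect_params")(bw$grads)
  params <- nn("collect_params")(est[c("stem", "stages", "head")])
  loss_fn <- make_loss_fn(est, X, Y)
  eps <- 1e-5
  set.seed(8)
  for (i in seq_along(params)) {
    # probe a few random entries of every parameter array
    probes <- sample(length(params[[i]]), min(4, length(params[[i]])))
    for (j in probes) {
      pp <- params; pp[[i]][j] <- pp[[i]][j] + eps
      pm <- params; pm[[i]][j] <- pm[[i]][j] - eps
      fd <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      expect_equal(analytic[[i]][j], fd, tolerance = 1e-4,
                   info = sprintf("param %d entry %d", i, j))
    }
  }
})

test_that("analytic input gradients match finite differences", {
  est <- tiny_est(2)
  set.seed(9)
  X <- array(rnorm(2 * 20 * 2), c(2, 20, 2))
  Y <- matrix(rnorm(3 * 2), 3, 2)
  fw <- nn("resnet_forward")(est, X, training = TRUE)
  bw <- nn("resnet_backward")(est, fw$cache, huber_loss(fw$out, Y)$grad)
  eps <- 1e-5
  loss_at <- function(Xv) {
    fw2 <- nn("resnet_forward")(est, Xv, training = TRUE)
    huber_loss(fw2$out, Y)$loss
  }
  set.seed(10)
  for (j in sample(length(X), 12)) {
    Xp <- X; Xp[j] <- Xp[j] + eps
    Xm <- X; Xm[j] <- Xm[j] - eps
    fd <- (loss_at(Xp) - loss_at(Xm)) / (2 * eps)
    expect_equal(bw$dX[j], fd, tolerance = 1e-4)
  }
})

test_that("maxpool backward routes gradient to the argmax, including overlaps", {
  set.seed(11)
  X <- array(rnorm(2 * 9 * 2), c(2, 9, 2))
  fw <- nn("maxpool_forward")(X, k = 3L, stride = 2L, pad = 1L)
  dY <- array(rnorm(length(fw$out)), dim(fw$out))
  dX <- nn("maxpool_backward")(fw$cache, dY)
  eps <- 1e-6
  for (j in sample(length(X), 10)) {
    Xp <- X; Xp[j] <- Xp[j] + eps
    Xm <- X; Xm[j] <- Xm[j] - eps
    fp <- sum(nn("maxpool_forward")(Xp, 3L, 2L, 1L)$out * dY)
    fm <- sum(nn("maxpool_forward")(Xm, 3L, 2L, 1L)$out * dY)
    expect_equal(dX[j], (fp - fm) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("im2col/col2im are exact adjoints", {
  set.seed(12)
  for (case in list(c(k = 3, s = 1, p = 1, L = 8), c(k = 7, s = 1, p = 3, L = 10),
                    c(k = 3, s = 2, p = 1, L = 9), c(k = 1, s = 2, p = 0, L = 7))) {
    C <- 3; B <- 2; L <- case[["L"]]
    X <- array(rnorm(C * L * B), c(C, L, B))
    Xc <- nn("im2col")(X, case[["k"]], case[["s"]], case[["p"]])
    G <- matrix(rnorm(length(Xc)), nrow(Xc), ncol(Xc))
    back <- nn("col2im")(G, C, case[["k"]], L, B, case[["s"]], case[["p"]])
    # adjoint identity: <im2col(X), G> == <X, col2im(G)>
    expect_equal(sum(Xc * G), sum(X * back), tolerance = 1e-10)
  }
})

test_that("huber loss is quadratic inside delta and linear outside", {
  p <- matrix(c(0.5, 3, -2, 0), 2, 2)
  t_ <- matrix(0, 2, 2)
  hl <- huber_loss(p, t_, delta = 1)
  expect_equal(hl$loss, mean(c(0.5 * 0.25, 3 - 0.5, 2 - 0.5, 0)))
  expect_equal(hl$grad, matrix(c(0.5, 1, -1, 0), 2, 2) / 4)
})

test_that("Adam reduces a convex quadratic", {
  params <- list(matrix(c(5, -3), 1))
  state <- nn("adam_init")(params)
  for (i in 1:500) {
    grads <- list(2 * params[[1]])
    step <- nn("adam_step")(params, grads, state, lr = 0.05)
    params <- step$params; state <- step$state
  }
  expect_lt(sum(params[[1]]^2), 1e-3)
})

test_that("batch norm normalizes in train mode and tracks running stats", {
  bn <- nn("nn_batchnorm")(3)
  set.seed(13)
  X <- array(rnorm(3 * 50 * 4, mean = 2, sd = 3), c(3, 50, 4))
  fw <- nn("batchnorm_forward")(bn, X, training = TRUE)
  Ym <- matrix(fw$out, 3)
  expect_lt(max(abs(rowMeans(Ym))), 1e-8)
  expect_lt(max(abs(apply(Ym, 1, sd) - 1)), 1e-2)
  # after many passes the running stats approach the batch stats
  for (i in 1:200) {
    fw <- nn("batchnorm_forward")(bn, X, training = TRUE)
    bn <- fw$layer
  }
  expect_equal(bn$running_mean, rowMeans(matrix(X, 3)), tolerance = 1e-3)
})
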