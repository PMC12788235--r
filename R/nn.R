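# Minimal 1D neural-network engine on base BLAS.
#
# Batched activations are arrays of shape (channels, length, batch); dense
# features are matrices (features, batch). Convolution is im2col + one GEMM.
# Every layer exposes a forward returning (out, cache) and a backward mapping
# the upstream gradient to (input gradient, parameter gradients). Correctness
# is pinned by finite-difference gradient checks in the test suite.

# ---- im2col / col2im ---------------------------------------------------------

# X: (C, L, B) -> (C * k, L_out * B); column-major so channel varies fastest
im2col <- function(X, k, stride, pad) {
  d <- dim(X); C <- d[1]; L <- d[2]; B <- d[3]
  Lp <- L + 2L * pad
  L_out <- (Lp - k) %/% stride + 1L
  Xp <- array(0, c(C, Lp, B))
  Xp[, pad + seq_len(L), ] <- X
  out <- array(0, c(C, k, L_out, B))
  for (j in seq_len(k)) {
    idx <- seq.int(j, by = stride, length.out = L_out)
    sl <- Xp[, idx, , drop = FALSE]          # (C, L_out, B)
    dim(sl) <- c(C, 1L, L_out, B)
    out[, j, , ] <- sl
  }
  dim(out) <- c(C * k, L_out * B)
  out
}

# adjoint of im2col: scatter-add patch gradients back to input positions
col2im <- function(dXc, C, k, L, B, stride, pad) {
  Lp <- L + 2L * pad
  L_out <- (Lp - k) %/% stride + 1L
  dim(dXc) <- c(C, k, L_out, B)
  dXp <- array(0, c(C, Lp, B))
  for (j in seq_len(k)) {
    idx <- seq.int(j, by = stride, length.out = L_out)
    part <- dXc[, j, , , drop = FALSE]
    dim(part) <- c(C, L_out, B)
    dXp[, idx, ] <- dXp[, idx, , drop = FALSE] + part
  }
  dXp[, pad + seq_len(L), , drop = FALSE]
}

conv_out_len <- function(L, k, stride, pad) (L + 2L * pad - k) %/% stride + 1L

# ---- layers ------------------------------------------------------------------

nn_conv1d <- function(in_channels, out_channels, kernel, stride = 1L, pad = 0L) {
  fan_in <- in_channels * kernel
  W <- matrix(rnorm(out_channels * fan_in, 0, sqrt(2 / fan_in)),
              out_channels, fan_in)
  list(type = "conv1d", W = W, in_channels = in_channels,
       out_channels = out_channels, kernel = as.integer(kernel),
       stride = as.integer(stride), pad = as.integer(pad))
}

conv1d_forward <- function(layer, X) {
  d <- dim(X)
  Xc <- im2col(X, layer$kernel, layer$stride, layer$pad)
  Y <- layer$W %*% Xc
  L_out <- conv_out_len(d[2], layer$kernel, layer$stride, layer$pad)
  dim(Y) <- c(layer$out_channels, L_out, d[3])
  list(out = Y, cache = list(Xc = Xc, in_dim = d))
}

conv1d_backward <- function(layer, cache, dY) {
  d <- dim(dY)
  dim(dY) <- c(d[1], d[2] * d[3])
  dW <- dY %*% t(cache$Xc)
  dXc <- crossprod(layer$W, dY)
  dX <- col2im(dXc, cache$in_dim[1], layer$kernel, cache$in_dim[2],
               cache$in_dim[3], layer$stride, layer$pad)
  list(dX = dX, grads = list(W = dW))
}

nn_batchnorm <- function(channels, eps = 1e-5, momentum = 0.1) {
  list(type = "batchnorm", gamma = rep(1, channels), beta = rep(0, channels),
       running_mean = rep(0, channels), running_var = rep(1, channels),
       eps = eps, momentum = momentum, channels = channels)
}

batchnorm_forward <- function(layer, X, training) {
  d <- dim(X)
  Xm <- X; dim(Xm) <- c(d[1], d[2] * d[3])
  if (training) {
    mu <- rowMeans(Xm)
    v <- rowMeans(Xm^2) - mu^2          # biased, used for normalization
    n <- ncol(Xm)
    unb <- if (n > 1) v * n / (n - 1) else v
    layer$running_mean <- (1 - layer$momentum) * layer$running_mean + layer$momentum * mu
    layer$running_var <- (1 - layer$momentum) * layer$running_var + layer$momentum * unb
  } else {
    mu <- layer$running_mean
    v <- layer$running_var
  }
  inv_sd <- 1 / sqrt(v + layer$eps)
  xhat <- (Xm - mu) * inv_sd
  Y <- layer$gamma * xhat + layer$beta
  dim(Y) <- d
  list(out = Y, cache = list(xhat = xhat, inv_sd = inv_sd, dims = d,
                             training = training),
       layer = layer)                    # running stats updated
}

batchnorm_backward <- function(layer, cache, dY) {
  d <- cache$dims
  dYm <- dY; dim(dYm) <- c(d[1], d[2] * d[3])
  xhat <- cache$xhat
  dgamma <- rowSums(dYm * xhat)
  dbeta <- rowSums(dYm)
  if (cache$training) {
    coef <- layer$gamma * cache$inv_sd
    dX <- coef * (dYm - rowMeans(dYm) - xhat * rowMeans(dYm * xhat))
  } else {
    dX <- (layer$gamma * cache$inv_sd) * dYm
  }
  dim(dX) <- d
  list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
}

gelu_forward <- function(X) {
  list(out = X * pnorm(X), cache = X)
}

gelu_backward <- function(cache, dY) {
  dY * (pnorm(cache) + cache * dnorm(cache))
}

maxpool_forward <- function(X, k = 3L, stride = 2L, pad = 1L) {
  d <- dim(X); C <- d[1]; L <- d[2]; B <- d[3]
  Lp <- L + 2L * pad
  L_out <- (Lp - k) %/% stride + 1L
  Xp <- array(-Inf, c(C, Lp, B))
  Xp[, pad + seq_len(L), ] <- X
  best <- array(-Inf, c(C, L_out, B))
  arg <- array(1L, c(C, L_out, B))
  for (j in seq_len(k)) {
    idx <- seq.int(j, by = stride, length.out = L_out)
    cand <- Xp[, idx, , drop = FALSE]
    dim(cand) <- c(C, L_out, B)
    better <- cand > best
    best[better] <- cand[better]
    arg[better] <- j
  }
  list(out = best, cache = list(arg = arg, in_dim = d, k = k,
                                stride = stride, pad = pad, L_out = L_out))
}

maxpool_backward <- function(cache, dY) {
  d <- cache$in_dim
  Lp <- d[2] + 2L * cache$pad
  dXp <- array(0, c(d[1], Lp, d[3]))
  for (j in seq_len(cache$k)) {
    idx <- seq.int(j, by = cache$stride, length.out = cache$L_out)
    m <- dY * (cache$arg == j)
    dXp[, idx, ] <- dXp[, idx, , drop = FALSE] + m
  }
  dXp[, cache$pad + seq_len(d[2]), , drop = FALSE]
}

# global average pool over time: (C, L, B) -> (C, B)
gap_forward <- function(X) {
  d <- dim(X)
  Xa <- aperm(X, c(2L, 1L, 3L))
  dim(Xa) <- c(d[2], d[1] * d[3])
  list(out = matrix(colMeans(Xa), d[1], d[3]), cache = d)
}

gap_backward <- function(cache, dY) {
  d <- cache
  dX <- array(0, d)
  for (b in seq_len(d[3])) dX[, , b] <- matrix(dY[, b] / d[2], d[1], d[2])
  dX
}

nn_linear <- function(in_features, out_features) {
  bound <- 1 / sqrt(in_features)
  list(type = "linear",
       W = matrix(runif(out_features * in_features, -bound, bound),
                  out_features, in_features),
       b = runif(out_features, -bound, bound))
}

linear_forward <- function(layer, X) {
  list(out = layer$W %*% X + layer$b, cache = X)
}

linear_backward <- function(layer, cache, dY) {
  list(dX = crossprod(layer$W, dY),
       grads = list(W = dY %*% t(cache), b = rowSums(dY)))
}

dropout_forward <- function(X, p, training) {
  if (!training || p <= 0) return(list(out = X, cache = NULL))
  mask <- (runif(length(X)) >= p) / (1 - p)
  dim(mask) <- dim(X)
  list(out = X * mask, cache = mask)
}

dropout_backward <- function(cache, dY) {
  if (is.null(cache)) dY else dY * cache
}

# ---- loss --------------------------------------------------------------------

#' Huber loss and its gradient
#'
#' Quadratic within `delta` of zero, linear beyond; evaluated element-wise on
#' standardized targets and averaged over all elements.
#'
#' @param pred,target Numeric matrices of equal shape.
#' @param delta Transition point (default 1, on standardized targets).
#' @return List with `loss` (scalar) and `grad` (matrix, d loss / d pred).
#' @export
huber_loss <- function(pred, target, delta = 1) {
  e <- pred - target
  a <- abs(e)
  quad <- a <= delta
  l <- ifelse(quad, 0.5 * e^2, delta * (a - 0.5 * delta))
  g <- ifelse(quad, e, delta * sign(e)) / length(e)
  list(loss = mean(l), grad = g)
}

# ---- parameter plumbing ------------------------------------------------------

PARAM_FIELDS <- c("W", "b", "gamma", "beta")

# walk a nested layer structure, applying f(layer) to every list that has a
# `type`; f returns the (possibly modified) layer
walk_layers <- function(x, f) {
  if (is.list(x)) {
    if (!is.null(x$type)) return(f(x))
    for (i in seq_along(x)) x[[i]] <- walk_layers(x[[i]], f)
  }
  x
}

collect_params <- function(layers) {
  out <- list()
  walk_layers(layers, function(l) {
    for (p in PARAM_FIELDS) {
      if (!is.null(l[[p]])) out[[length(out) + 1L]] <<- l[[p]]
    }
    l
  })
  out
}

# replace parameters in the same traversal order
inject_params <- function(layers, params) {
  i <- 0L
  walk_layers(layers, function(l) {
    for (p in PARAM_FIELDS) {
      if (!is.null(l[[p]])) {
        i <<- i + 1L
        v <- params[[i]]
        dim(v) <- dim(l[[p]])
        l[[p]] <- v
      }
    }
    l
  })
}

n_params <- function(layers) {
  sum(vapply(collect_params(layers), length, integer(1)))
}

BUFFER_FIELDS <- c("running_mean", "running_var")

# batch-norm running statistics, in the same traversal order as the C++ path
collect_buffers <- function(layers) {
  out <- list()
  walk_layers(layers, function(l) {
    for (p in BUFFER_FIELDS) {
      if (!is.null(l[[p]])) out[[length(out) + 1L]] <<- l[[p]]
    }
    l
  })
  out
}

inject_buffers <- function(layers, buffers) {
  i <- 0L
  walk_layers(layers, function(l) {
    for (p in BUFFER_FIELDS) {
      if (!is.null(l[[p]])) {
        i <<- i + 1L
        l[[p]] <- as.numeric(buffers[[i]])
      }
    }
    l
  })
}

# ---- Adam --------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * grads[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * grads[[i]]^2
    params[[i]] <- params[[i]] -
      lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  list(params = params, state = state)
}
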