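# The 1D residual network that regresses six joint angles from a 6 x 200 IMU
# window. Architecture: conv stem (k7/s1, 64 ch) -> BN -> GELU -> maxpool
# (k3/s2) -> four residual stages of two BasicBlocks (64/128/256/512 channels,
# stride-2 first block in stages 2-4) -> global average pooling -> head of
# three Linear -> GELU -> Dropout(0.2) layers (256/128/64) -> linear output
# (6). Convolutions carry no bias (each is followed by batch norm); the skip
# path of a shape-changing block is a 1x1 convolution + BN; linear layers are
# biased. This is the unique standard configuration matching the published
# parameter count of 4,019,014.

#' Declarative architecture description
#'
#' @param in_channels Input channels (6 IMU channels).
#' @param input_len Window length in frames (200 = 2 s at 100 Hz).
#' @param out_dim Output dimension (6 joint angles).
#' @param width_multiplier Scales every stage and head width (1 = published
#'   scale; fractions give desk-scale models for fast experiments). Widths are
#'   rounded to at least one unit.
#' @param dropout Dropout probability in the regression head.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(in_channels = 6L, input_len = 200L, out_dim = 6L,
                       width_multiplier = 1, dropout = 0.2) {
  stopifnot_scalar_number(width_multiplier, "width_multiplier", min = 0,
                          strict_min = TRUE)
  w <- function(x) pmax(1L, as.integer(round(x * width_multiplier)))
  spec <- structure(
    list(
      in_channels = as.integer(in_channels),
      input_len = as.integer(input_len),
      out_dim = as.integer(out_dim),
      width_multiplier = width_multiplier,
      stem = list(channels = w(64), kernel = 7L, stride = 1L, pad = 3L),
      pool = list(kernel = 3L, stride = 2L, pad = 1L),
      stage_channels = w(c(64, 128, 256, 512)),
      blocks_per_stage = 2L,
      stage_strides = c(1L, 2L, 2L, 2L),
      head_widths = w(c(256, 128, 64)),
      dropout = dropout
    ),
    class = "model_spec"
  )
  lens <- feature_lengths(spec)
  if (any(lens < 1L)) {
    abort("`input_len` too short to survive the four downsampling steps.")
  }
  spec
}

#' Temporal feature lengths through the network
#'
#' Closed-form cascade of the length arithmetic
#' `L_out = floor((L + 2 pad - k) / stride) + 1`: stem conv, max pool, then
#' the four stages. At the published scale with a 200-frame input this is
#' `c(200, 100, 100, 50, 25, 13)`.
#'
#' @param spec A [model_spec()].
#' @return Integer vector of length 6.
#' @export
feature_lengths <- function(spec) {
  L <- conv_out_len(spec$input_len, spec$stem$kernel, spec$stem$stride,
                    spec$stem$pad)
  lens <- L
  L <- conv_out_len(L, spec$pool$kernel, spec$pool$stride, spec$pool$pad)
  lens <- c(lens, L)
  for (s in seq_along(spec$stage_channels)) {
    L <- conv_out_len(L, 3L, spec$stage_strides[s], 1L)
    lens <- c(lens, L)
  }
  lens
}

new_basic_block <- function(in_ch, out_ch, stride) {
  block <- list(
    conv1 = nn_conv1d(in_ch, out_ch, 3L, stride = stride, pad = 1L),
    bn1 = nn_batchnorm(out_ch),
    conv2 = nn_conv1d(out_ch, out_ch, 3L, stride = 1L, pad = 1L),
    bn2 = nn_batchnorm(out_ch)
  )
  if (stride != 1L || in_ch != out_ch) {
    block$downsample <- list(
      conv = nn_conv1d(in_ch, out_ch, 1L, stride = stride, pad = 0L),
      bn = nn_batchnorm(out_ch)
    )
  }
  block
}

#' Build the joint-angle estimation network
#'
#' Instantiates the architecture described by a [model_spec()], with weight
#' initialization driven entirely by `seed` (He-normal convolutions, uniform
#' fan-in linears, unit-gain batch norms).
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `joint_angle_estimator`.
#' @export
build_model <- function(spec = model_spec(), seed = 0L) {
  with_seed(derive_seed(seed, "init"), {
    stem <- list(conv = nn_conv1d(spec$in_channels, spec$stem$channels,
                                  spec$stem$kernel, spec$stem$stride,
                                  spec$stem$pad),
                 bn = nn_batchnorm(spec$stem$channels))
    stages <- list()
    in_ch <- spec$stem$channels
    for (s in seq_along(spec$stage_channels)) {
      out_ch <- spec$stage_channels[s]
      blocks <- list()
      for (b in seq_len(spec$blocks_per_stage)) {
        stride <- if (b == 1L) spec$stage_strides[s] else 1L
        blocks[[b]] <- new_basic_block(in_ch, out_ch, stride)
        in_ch <- out_ch
      }
      stages[[s]] <- blocks
    }
    widths <- c(in_ch, spec$head_widths)
    fc <- purrr::map(seq_len(3), function(i) nn_linear(widths[i], widths[i + 1]))
    out_layer <- nn_linear(widths[4], spec$out_dim)
    structure(
      list(spec = spec, stem = stem, stages = stages,
           head = list(fc = fc, out_layer = out_layer)),
      class = "joint_angle_estimator"
    )
  })
}

#' Count trainable parameters
#'
#' Trainable scalars only: convolution and linear weights, linear biases and
#' batch-norm affine parameters; running statistics are buffers and excluded.
#'
#' @param est A `joint_angle_estimator`.
#' @return Integer count.
#' @export
count_parameters <- function(est) {
  n_params(est[c("stem", "stages", "head")])
}

#' @export
print.joint_angle_estimator <- function(x, ...) {
  cat(sprintf(
    "<joint_angle_estimator> %d-ch x %d input -> %d outputs, %s parameters (width x%g)\n",
    x$spec$in_channels, x$spec$input_len, x$spec$out_dim,
    format(count_parameters(x), big.mark = ","), x$spec$width_multiplier
  ))
  invisible(x)
}

# ---- forward / backward ------------------------------------------------------

block_forward <- function(block, X, training) {
  c1 <- conv1d_forward(block$conv1, X)
  b1 <- batchnorm_forward(block$bn1, c1$out, training)
  block$bn1 <- b1$layer
  g1 <- gelu_forward(b1$out)
  c2 <- conv1d_forward(block$conv2, g1$out)
  b2 <- batchnorm_forward(block$bn2, c2$out, training)
  block$bn2 <- b2$layer
  if (!is.null(block$downsample)) {
    dc <- conv1d_forward(block$downsample$conv, X)
    db <- batchnorm_forward(block$downsample$bn, dc$out, training)
    block$downsample$bn <- db$layer
    short <- db$out
    ds_cache <- list(dc = dc$cache, db = db$cache)
  } else {
    short <- X
    ds_cache <- NULL
  }
  s <- b2$out + short
  g2 <- gelu_forward(s)
  list(out = g2$out, block = block,
       cache = list(c1 = c1$cache, b1 = b1$cache, g1 = g1$cache,
                    c2 = c2$cache, b2 = b2$cache, ds = ds_cache,
                    g2 = g2$cache))
}

block_backward <- function(block, cache, dY) {
  dS <- gelu_backward(cache$g2, dY)
  b2 <- batchnorm_backward(block$bn2, cache$b2, dS)
  c2 <- conv1d_backward(block$conv2, cache$c2, b2$dX)
  dG1 <- gelu_backward(cache$g1, c2$dX)
  b1 <- batchnorm_backward(block$bn1, cache$b1, dG1)
  c1 <- conv1d_backward(block$conv1, cache$c1, b1$dX)
  grads <- list(
    conv1 = list(type = "conv1d", W = c1$grads$W),
    bn1 = list(type = "batchnorm", gamma = b1$grads$gamma, beta = b1$grads$beta),
    conv2 = list(type = "conv1d", W = c2$grads$W),
    bn2 = list(type = "batchnorm", gamma = b2$grads$gamma, beta = b2$grads$beta)
  )
  if (!is.null(block$downsample)) {
    db <- batchnorm_backward(block$downsample$bn, cache$ds$db, dS)
    dc <- conv1d_backward(block$downsample$conv, cache$ds$dc, db$dX)
    grads$downsample <- list(
      conv = list(type = "conv1d", W = dc$grads$W),
      bn = list(type = "batchnorm", gamma = db$grads$gamma, beta = db$grads$beta)
    )
    dX <- c1$dX + dc$dX
  } else {
    dX <- c1$dX + dS
  }
  list(dX = dX, grads = grads)
}

# full forward pass; returns output, per-layer caches, and the estimator with
# updated batch-norm running statistics (only changed when training = TRUE)
resnet_forward <- function(est, X, training = FALSE) {
  if (length(dim(X)) == 2L) dim(X) <- c(dim(X), 1L)
  d <- dim(X)
  if (d[1] != est$spec$in_channels || d[2] != est$spec$input_len) {
    abort(sprintf("input must be (%d, %d, batch); got (%s)",
                  est$spec$in_channels, est$spec$input_len,
                  paste(d, collapse = ", ")))
  }
  c0 <- conv1d_forward(est$stem$conv, X)
  b0 <- batchnorm_forward(est$stem$bn, c0$out, training)
  est$stem$bn <- b0$layer
  g0 <- gelu_forward(b0$out)
  p0 <- maxpool_forward(g0$out, est$spec$pool$kernel, est$spec$pool$stride,
                        est$spec$pool$pad)
  h <- p0$out
  stage_caches <- list()
  stage_lens <- integer(length(est$stages))
  for (s in seq_along(est$stages)) {
    block_caches <- list()
    for (b in seq_along(est$stages[[s]])) {
      bf <- block_forward(est$stages[[s]][[b]], h, training)
      est$stages[[s]][[b]] <- bf$block
      block_caches[[b]] <- bf$cache
      h <- bf$out
    }
    stage_caches[[s]] <- block_caches
    stage_lens[s] <- dim(h)[2]
  }
  gp <- gap_forward(h)
  z <- gp$out
  head_caches <- list()
  for (i in seq_len(3)) {
    lf <- linear_forward(est$head$fc[[i]], z)
    gf <- gelu_forward(lf$out)
    df <- dropout_forward(gf$out, est$spec$dropout, training)
    head_caches[[i]] <- list(l = lf$cache, g = gf$cache, d = df$cache)
    z <- df$out
  }
  of <- linear_forward(est$head$out_layer, z)
  list(out = of$out, est = est,
       cache = list(c0 = c0$cache, b0 = b0$cache, g0 = g0$cache,
                    p0 = p0$cache, stages = stage_caches, gap = gp$cache,
                    head = head_caches, out = of$cache),
       stage_lengths = c(dim(c0$out)[2], dim(p0$out)[2], stage_lens))
}

resnet_backward <- function(est, cache, dOut) {
  ob <- linear_backward(est$head$out_layer, cache$out, dOut)
  grads_head_fc <- vector("list", 3)
  dz <- ob$dX
  for (i in 3:1) {
    hc <- cache$head[[i]]
    dd <- dropout_backward(hc$d, dz)
    dg <- gelu_backward(hc$g, dd)
    lb <- linear_backward(est$head$fc[[i]], hc$l, dg)
    grads_head_fc[[i]] <- list(type = "linear", W = lb$grads$W, b = lb$grads$b)
    dz <- lb$dX
  }
  dh <- gap_backward(cache$gap, dz)
  grads_stages <- vector("list", length(est$stages))
  for (s in rev(seq_along(est$stages))) {
    blocks <- est$stages[[s]]
    gblocks <- vector("list", length(blocks))
    for (b in rev(seq_along(blocks))) {
      bb <- block_backward(blocks[[b]], cache$stages[[s]][[b]], dh)
      gblocks[[b]] <- bb$grads
      dh <- bb$dX
    }
    grads_stages[[s]] <- gblocks
  }
  dp <- maxpool_backward(cache$p0, dh)
  dg0 <- gelu_backward(cache$g0, dp)
  b0 <- batchnorm_backward(est$stem$bn, cache$b0, dg0)
  c0 <- conv1d_backward(est$stem$conv, cache$c0, b0$dX)
  grads <- list(
    stem = list(conv = list(type = "conv1d", W = c0$grads$W),
                bn = list(type = "batchnorm", gamma = b0$grads$gamma,
                          beta = b0$grads$beta)),
    stages = grads_stages,
    head = list(fc = grads_head_fc,
                out_layer = list(type = "linear", W = ob$grads$W,
                                 b = ob$grads$b))
  )
  list(dX = c0$dX, grads = grads)
}

#' Forward pass in evaluation mode
#'
#' Dropout is disabled and batch-norm running statistics are used, so two
#' passes over the same batch are bitwise identical.
#'
#' @param est A `joint_angle_estimator`.
#' @param X Input array `(6, input_len, N)` (standardized units).
#' @param batch_size Windows per forward chunk.
#' @param engine `"cpp"` (compiled fused pass) or `"r"` (reference
#'   implementation); both produce the same numbers.
#' @return Matrix `(N, out_dim)` of standardized predictions.
#' @export
predict_windows <- function(est, X, batch_size = 512L,
                            engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (length(dim(X)) == 2L) dim(X) <- c(dim(X), 1L)
  d <- dim(X)
  if (d[1] != est$spec$in_channels || d[2] != est$spec$input_len) {
    abort(sprintf("input must be (%d, %d, batch); got (%s)",
                  est$spec$in_channels, est$spec$input_len,
                  paste(d, collapse = ", ")))
  }
  n <- d[3]
  out <- matrix(0, n, est$spec$out_dim)
  core <- est[c("stem", "stages", "head")]
  if (engine == "cpp") {
    params <- collect_params(core)
    buffers <- collect_buffers(core)
  }
  at <- 1L
  while (at <= n) {
    idx <- at:min(n, at + batch_size - 1L)
    if (engine == "cpp") {
      out[idx, ] <- t(cpp_predict(params, buffers, X[, , idx, drop = FALSE],
                                  unclass(est$spec)))
    } else {
      fw <- resnet_forward(est, X[, , idx, drop = FALSE], training = FALSE)
      out[idx, ] <- t(fw$out)
    }
    at <- at + batch_size
  }
  colnames(out) <- ANGLE_CHANNELS[seq_len(min(6, est$spec$out_dim))]
  out
}

#' Probe the realized temporal lengths of a built network
#'
#' Runs one input through the network and reads the time dimension after the
#' stem convolution, the max pool and each residual stage.
#'
#' @param est A `joint_angle_estimator`.
#' @return Integer vector of 6 lengths (stem conv, max pool, stages 1-4).
#' @export
probe_feature_lengths <- function(est) {
  X <- array(0, c(est$spec$in_channels, est$spec$input_len, 1L))
  resnet_forward(est, X, training = FALSE)$stage_lengths
}

#' Layer table and parameter count, in the style of the architecture table
#'
#' @param spec A [model_spec()].
#' @param seed Seed used to instantiate the counted model.
#' @return A tibble with one row per layer group, invisibly; the table is also
#'   printed.
#' @export
model_summary <- function(spec = model_spec(), seed = 0L) {
  est <- build_model(spec, seed)
  lens <- feature_lengths(spec)
  ch <- spec$stage_channels
  tbl <- tibble::tibble(
    layer = c("Input", "Conv1D -> BN -> GELU", "MaxPool1D",
              paste0("Stage ", 1:4, ": BasicBlock x2"),
              "GlobalAvgPool1D",
              "Linear -> GELU -> Dropout x3", "Linear (Output)"),
    channels = c(spec$in_channels, spec$stem$channels, spec$stem$channels,
                 ch, ch[4], NA, NA),
    output = c(
      sprintf("%dx%d", spec$in_channels, spec$input_len),
      sprintf("%dx%d", spec$stem$channels, lens[1]),
      sprintf("%dx%d", spec$stem$channels, lens[2]),
      sprintf("%dx%d", ch, lens[3:6]),
      sprintf("%d", ch[4]),
      paste(spec$head_widths, collapse = "->"),
      sprintf("%d", spec$out_dim)
    )
  )
  print(as.data.frame(tbl), row.names = FALSE)
  n <- count_parameters(est)
  cat(sprintf("Trainable parameters: %s (FP32 size %.2f MB)\n",
              format(n, big.mark = ","), n * 4 / 2^20))
  invisible(tbl)
}

#' FP32 checkpoint size implied by a parameter count
#'
#' @param n_parameters Trainable parameter count.
#' @return Size in MB (MiB convention, 4 bytes per parameter).
#' @export
model_size_mb <- function(n_parameters) n_parameters * 4 / 2^20
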