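# Internal helpers: seeding, validation, RNG isolation.

#' Derive a child seed from a parent seed and a stream label
#'
#' All randomness in the package flows from one user-supplied seed; independent
#' stages (participants, runs, gap processes) draw from child seeds produced by
#' hashing the parent seed together with a label, so adding a stage never
#' perturbs the stream of another.
#'
#' @param seed Parent integer seed.
#' @param ... Labels (coerced to character) identifying the child stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, ...) {
  label <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(label)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

# evaluate `expr` under `seed` without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_min && x <= min) abort(sprintf("`%s` must be > %s.", name, min))
  if (!strict_min && x < min) abort(sprintf("`%s` must be >= %s.", name, min))
  invisible(x)
}

# half-open interval utilities for segment bookkeeping; segments are stored as
# a 2-column integer matrix (start, end), 1-based, end exclusive
segments_from_mask <- function(valid) {
  n <- length(valid)
  if (n == 0L || !any(valid)) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep] + 1L)
}

segment_lengths <- function(segments) {
  if (nrow(segments) == 0L) return(integer(0))
  segments[, "end"] - segments[, "start"]
}
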