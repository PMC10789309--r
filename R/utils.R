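# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
# All user-facing stochastic entry points funnel through this so that a given
# seed argument fully determines the result without clobbering the session RNG.
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed from a user seed, kept inside 32-bit
# integer range.
child_seed <- function(seed, stream) {
  (as.double(seed) * 1009 + stream * 9973) %% 2147483647
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Numerically stable row-wise softmax / log-softmax on a matrix.
# max.col (C code) is much faster than apply(S, 1, max) in the hot loop.
row_max <- function(S) S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]

row_softmax <- function(S) {
  E <- exp(S - row_max(S))
  E / rowSums(E)
}

row_log_softmax <- function(S) {
  M <- S - row_max(S)
  M - log(rowSums(exp(M)))
}

# Stacked-batch representation: a (m, n, dim) tensor is stored sample-major as
# a (m*n, dim) matrix; rows ((i-1)*n + 1) .. (i*n) belong to sample i.
stack_rows <- function(arr3) {
  stopifnot(length(dim(arr3)) == 3L)
  m <- dim(arr3)[1L]; n <- dim(arr3)[2L]; d <- dim(arr3)[3L]
  out <- matrix(0, m * n, d)
  for (i in seq_len(m)) out[((i - 1L) * n + 1L):(i * n), ] <- arr3[i, , ]
  out
}

unstack_rows <- function(X, m, n) {
  d <- ncol(X)
  arr <- array(0, dim = c(m, n, d))
  for (i in seq_len(m)) arr[i, , ] <- X[((i - 1L) * n + 1L):(i * n), , drop = FALSE]
  arr
}

# Rows of a stacked matrix holding timestep t for every sample.
timestep_rows <- function(m, n, t) (seq_len(m) - 1L) * n + t

assert_records <- function(records, arg = "records") {
  if (!is.data.frame(records) || !all(c("id", "seq") %in% names(records))) {
    stop(sprintf("`%s` must be a data frame with columns `id` and `seq`", arg),
         call. = FALSE)
  }
  invisible(records)
}
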