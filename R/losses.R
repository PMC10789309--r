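# Cross-view predictive loss and supervised losses.

# Internal: loss (and optionally gradients) of one directed cross-view term
# on stacked encodings. For each timestep t the m x m score matrix is
# S_t[i, j] = <W_t c_a[i], z_b[t, j]>; log-softmax runs across j (the batch
# axis — other samples at the same timestep are the negatives), the diagonal
# (matching-sample) scores are averaged over the batch and timesteps, negated.
cv_term <- function(c_a, Zb, m, n, W, want_grad = FALSE) {
  shared <- length(W) == 1L
  loss <- 0
  if (want_grad) {
    dC <- matrix(0, m, ncol(c_a))
    dZ <- matrix(0, m * n, ncol(Zb))
    dW <- lapply(W, function(w) w * 0)
  }
  for (t in seq_len(n)) {
    Wt <- if (shared) W[[1L]] else W[[t]]
    rows <- timestep_rows(m, n, t)
    Zt <- Zb[rows, , drop = FALSE]
    P <- tcrossprod(c_a, Wt)          # P[i, ] = W_t c_a[i]
    S <- tcrossprod(P, Zt)
    if (any(!is.finite(S))) stop("non-finite cross-view scores", call. = FALSE)
    LS <- row_log_softmax(S)
    loss <- loss - mean(diag(LS))
    if (want_grad) {
      G <- (row_softmax(S) - diag(m)) / (n * m)
      dP <- G %*% Zt
      dC <- dC + dP %*% Wt
      dZ[rows, ] <- dZ[rows, ] + crossprod(G, P)
      k <- if (shared) 1L else t
      dW[[k]] <- dW[[k]] + crossprod(dP, c_a)
    }
  }
  loss <- loss / n
  if (want_grad) list(loss = loss, dC = dC, dZ = dZ, dW = dW) else list(loss = loss)
}

#' Cross-view predictive loss for one directed view pair
#'
#' Measures how well one view's per-sample context vector `c_a` identifies the
#' matching sample's per-position encoding in another view `z_b`, against the
#' other samples of the batch as negatives. For each timestep `t` a linear map
#' `W_t` projects the context; scores against all samples' `z_b[, t, ]` go
#' through a log-softmax over the batch and the matching-sample diagonal is
#' averaged and negated. With a single sample there are no negatives and the
#' loss is exactly 0; it is always non-negative.
#'
#' @param c_a Context matrix `(m, dim)` of the predicting view.
#' @param z_b Encoded array `(m, n, dim)` of the predicted view.
#' @param heads List of `n` (or 1 shared) `dim x dim` matrices `W_t`.
#' @return Scalar loss.
#' @export
#' @examples
#' crossview_loss(matrix(0, 2, 3), array(0, c(2, 1, 3)),
#'                list(diag(3)))  # uniform logits: log(2)
crossview_loss <- function(c_a, z_b, heads) {
  stopifnot(is.matrix(c_a), length(dim(z_b)) == 3L, dim(z_b)[1] == nrow(c_a))
  m <- nrow(c_a)
  if (m < 1L) stop("empty batch", call. = FALSE)
  n <- dim(z_b)[2]
  if (!is.list(heads)) heads <- list(heads)
  if (length(heads) != n && length(heads) != 1L) {
    stop("need one head per timestep (or a single shared head)", call. = FALSE)
  }
  cv_term(c_a, stack_rows(z_b), m, n, heads)$loss
}

#' Total self-supervised loss over configured view pairs
#'
#' Sums [crossview_loss()] over every ordered view pair. The default pairing
#' is the two-term objective over the embedding and EIIP views (each predicts
#' the other); an all-pairs mode over three views uses all six ordered pairs.
#'
#' @param enc Named list of views; each element has `$c` (matrix `(m, dim)`)
#'   and `$z` (array `(m, n, dim)`).
#' @param heads Named list of head lists, one per ordered pair, named
#'   `"a->b"`.
#' @param pairs List of length-2 character vectors `c(from, to)`; default is
#'   every ordered pair of the views present in `enc`.
#' @return Scalar total loss.
#' @export
total_ssl_loss <- function(enc, heads, pairs = NULL) {
  if (length(enc) < 2L) stop("need at least two views", call. = FALSE)
  pairs <- pairs %||% {
    vs <- names(enc)
    combs <- expand.grid(from = vs, to = vs, stringsAsFactors = FALSE)
    combs <- combs[combs$from != combs$to, ]
    lapply(seq_len(nrow(combs)), function(i) c(combs$from[i], combs$to[i]))
  }
  total <- 0
  for (p in pairs) {
    key <- paste0(p[1], "->", p[2])
    total <- total + crossview_loss(enc[[p[1]]]$c, enc[[p[2]]]$z, heads[[key]])
  }
  total
}

#' Two-class projection head probabilities
#'
#' `softmax(W2 relu(W1 c + b1) + b2)` applied row-wise: a two-layer projection
#' head on the fused context vector followed by softmax normalization over the
#' two classes.
#'
#' @param c_all Context matrix `(m, dim)`.
#' @param head List with `W1`, `b1`, `W2`, `b2`.
#' @return Matrix `(m, 2)` of class probabilities; rows sum to 1. Column 2 is
#'   the positive (bound) class.
#' @export
classify <- function(c_all, head) {
  H <- pmax(add_bias(c_all %*% head$W1, head$b1), 0)
  logits <- add_bias(H %*% head$W2, head$b2)
  if (any(!is.finite(logits))) stop("non-finite classifier logits", call. = FALSE)
  row_softmax(logits)
}

#' Mean binary cross-entropy
#'
#' `-(1/m) * sum(y * log(p) + (1 - y) * log(1 - p))` with probabilities
#' clamped at `1e-12` before the log.
#'
#' @param y Binary labels `(m,)`.
#' @param y_hat_pos Predicted probability of class 1, `(m,)`.
#' @return Scalar loss, non-negative.
#' @export
#' @examples
#' cross_entropy(c(1, 0), c(0.5, 0.5))  # log(2)
cross_entropy <- function(y, y_hat_pos) {
  if (length(y) != length(y_hat_pos)) stop("length mismatch", call. = FALSE)
  p <- clamp(y_hat_pos, 1e-12, 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
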