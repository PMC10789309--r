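# Layer norm, attention and the pre-norm transformer.

test_that("layer_norm matches the closed form and a mean/variance oracle", {
  expect_equal(layer_norm(c(1, 2, 3), rep(1, 3), rep(0, 3), eps = 0),
               c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  set.seed(8)
  for (rep in 1:20) {
    z <- rnorm(sample(3:12, 1))
    g <- rnorm(length(z)); b <- rnorm(length(z))
    mu <- mean(z); v <- mean((z - mu)^2)
    oracle <- (z - mu) / sqrt(v + 1e-5) * g + b
    expect_equal(layer_norm(z, g, b), oracle, tolerance = 1e-6)
  }
})

test_that("layer_norm degenerate cases: constant input and zero scale", {
  expect_equal(layer_norm(rep(5, 4), rep(1, 4), rep(2, 4)), rep(2, 4))
  z <- rnorm(6)
  expect_equal(layer_norm(z, rep(0, 6), rep(0.3, 6)), rep(0.3, 6))
})

# Brute-force attention oracle: explicit loops over heads and query positions.
mha_oracle <- function(X, heads, Wo = NULL) {
  n <- nrow(X); d <- ncol(X); dh <- d / heads
  Wo <- if (is.null(Wo)) diag(d) else Wo
  O <- matrix(0, n, d)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    for (q in seq_len(n)) {
      scores <- sapply(seq_len(n), function(j) {
        sum(X[q, cols] * X[j, cols]) / sqrt(dh)
      })
      w <- exp(scores - max(scores)); w <- w / sum(w)
      O[q, cols] <- colSums(X[, cols, drop = FALSE] * w)
    }
  }
  O %*% Wo
}

test_that("multi-head attention equals the per-head brute-force loop", {
  set.seed(13)
  for (heads in c(1, 2, 4)) {
    X <- matrix(rnorm(5 * 8), 5, 8)
    Wo <- matrix(rnorm(64), 8, 8)
    got <- multi_head_attention(X, X, X, heads = heads, Wo = Wo)
    expect_equal(got, mha_oracle(X, heads, Wo), tolerance = 1e-5)
  }
  # batch form: each sample independently
  Xb <- array(rnorm(2 * 5 * 8), c(2, 5, 8))
  got <- multi_head_attention(Xb, Xb, Xb, heads = 2)
  for (i in 1:2) {
    expect_equal(got[i, , ], mha_oracle(matrix(Xb[i, , ], 5, 8), 2),
                 tolerance = 1e-5)
  }
})

test_that("identical keys give uniform attention: output is the value mean", {
  set.seed(4)
  n <- 6; d <- 4
  K <- matrix(rep(rnorm(d), each = n), n, d)     # all key rows identical
  Q <- matrix(rnorm(n * d), n, d)
  V <- matrix(rnorm(n * d), n, d)
  out <- multi_head_attention(Q, K, V, heads = 1)
  expect_equal(out, matrix(rep(colMeans(V), each = n), n, d), tolerance = 1e-8)
})

test_that("length-one sequences get attention weight exactly 1", {
  Q <- matrix(rnorm(4), 1, 4)
  V <- matrix(rnorm(4), 1, 4)
  expect_equal(multi_head_attention(Q, Q, V, heads = 2), V)
})

test_that("attention weight rows sum to 1 inside the training path", {
  set.seed(9)
  spec <- tiny_spec()
  lp <- circrbp:::init_transformer(spec, 5)$layers[[1]]
  Xn <- matrix(rnorm(2 * 5 * spec$dim), 10, spec$dim)
  att <- circrbp:::mha_fwd(Xn, m = 2, n1 = 5, lp, heads = spec$heads)
  for (A in att$A_list) expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-6)
})

test_that("dim not divisible by heads is rejected", {
  expect_error(model_spec(dim = 10, heads = 3), "divisible")
  expect_error(multi_head_attention(matrix(0, 2, 5), matrix(0, 2, 5),
                                    matrix(0, 2, 5), heads = 2), "divisible")
})

test_that("zero attention/FFN weights make the transformer the identity", {
  set.seed(2)
  spec <- tiny_spec()
  tf <- zeroed_transformer(circrbp:::init_transformer(spec, 6))
  z <- array(rnorm(3 * 6 * spec$dim), c(3, 6, spec$dim))
  out <- transformer_forward(z, tf, spec)
  expect_equal(out$h, z, tolerance = 1e-12)
  expect_equal(out$c, matrix(rep(tf$c0, each = 3), 3), tolerance = 1e-12)
})

test_that("transformer output has contract shapes and is deterministic", {
  set.seed(6)
  spec <- tiny_spec()
  tf <- circrbp:::init_transformer(spec, 4)
  z <- array(rnorm(2 * 4 * spec$dim), c(2, 4, spec$dim))
  o1 <- transformer_forward(z, tf, spec)
  o2 <- transformer_forward(z, tf, spec)
  expect_identical(o1, o2)
  expect_equal(dim(o1$h), c(2, 4, spec$dim))
  expect_equal(dim(o1$c), c(2, spec$dim))
  expect_error(transformer_forward(z * NA, tf, spec), "finite")
})

test_that("permuting batch samples permutes outputs identically", {
  set.seed(7)
  spec <- tiny_spec()
  tf <- circrbp:::init_transformer(spec, 5)
  z <- array(rnorm(4 * 5 * spec$dim), c(4, 5, spec$dim))
  perm <- c(3, 1, 4, 2)
  o <- transformer_forward(z, tf, spec)
  op <- transformer_forward(z[perm, , , drop = FALSE], tf, spec)
  expect_equal(op$c, o$c[perm, ], tolerance = 1e-12)
  expect_equal(op$h, o$h[perm, , ], tolerance = 1e-12)
})

test_that("conv encoder obeys the shape contract with no cross-sample mixing", {
  set.seed(3)
  spec <- tiny_spec(pool = 2)
  enc <- circrbp:::init_conv_encoder(5, spec)
  L <- 12
  X2 <- matrix(rnorm(2 * L * 5), 2 * L, 5)
  f2 <- circrbp:::conv_encoder_fwd(X2, 2, L, enc, spec)
  expect_equal(dim(f2$out), c(2 * (L / 2), spec$dim))
  # zero input stays finite
  f0 <- circrbp:::conv_encoder_fwd(X2 * 0, 2, L, enc, spec)
  expect_true(all(is.finite(f0$out)))
  # doubling the batch leaves per-sample encodings unchanged
  X4 <- rbind(X2, X2)
  f4 <- circrbp:::conv_encoder_fwd(X4, 4, L, enc, spec)
  expect_equal(f4$out[1:(2 * L / 2), ], f2$out, tolerance = 1e-12)
})

test_that("parameter count is a pure function of the architecture spec", {
  count_for <- function(spec, c_in, n) {
    set.seed(1)
    p1 <- list(enc = circrbp:::init_conv_encoder(c_in, spec),
               tf = circrbp:::init_transformer(spec, n))
    set.seed(99)
    p2 <- list(enc = circrbp:::init_conv_encoder(c_in, spec),
               tf = circrbp:::init_transformer(spec, n))
    c(circrbp:::tree_param_count(p1), circrbp:::tree_param_count(p2))
  }
  counts <- count_for(tiny_spec(), 5, 6)
  expect_equal(counts[1], counts[2])
  # closed-form check for the tiny spec: one conv block (weights, bias and
  # channel layer norm) plus a one-layer transformer with context token
  conv_n <- 3 * 5 * 8 + 8 + 2 * 8
  tf_n <- 8 + 2 * (2 * 8) + 4 * 64 + (8 * 6 + 6) + (6 * 8 + 8)
  expect_equal(counts[1], conv_n + tf_n)
})

test_that("training-path gradients match finite differences", {
  set.seed(17)
  spec <- tiny_spec(conv_blocks = 2, pool = 2)
  m <- 3; L <- 12; n <- L %/% spec$pool
  Xv <- list(c2v = matrix(rnorm(m * L * 5), m * L, 5),
             eiip = matrix(rnorm(m * L * 2), m * L, 2))
  pairs <- list(c("c2v", "eiip"), c("eiip", "c2v"))
  keys <- c("c2v->eiip", "eiip->c2v")
  params <- list(enc = list(c2v = circrbp:::init_conv_encoder(5, spec),
                            eiip = circrbp:::init_conv_encoder(2, spec)),
                 tf = circrbp:::init_transformer(spec, n),
                 heads = circrbp:::init_heads(n, spec$dim, keys))
  an <- circrbp:::ssl_batch_grad(params, Xv, m, L, n, spec, pairs, keys)
  lossf <- function(p) {
    circrbp:::ssl_batch_grad(p, Xv, m, L, n, spec, pairs, keys,
                             want_grad = FALSE)$loss
  }
  # probe a few leaves spread over the parameter tree
  probes <- list(list("enc", "c2v", "blocks", 1L, "W"),
                 list("enc", "eiip", "blocks", 2L, "b"),
                 list("tf", "layers", 1L, "Wq"),
                 list("tf", "layers", 1L, "ln2_g"),
                 list("tf", "c0"),
                 list("heads", "c2v->eiip", 2L))
  eps <- 1e-5
  for (pt in probes) {
    leaf <- do.call(purrr::pluck, c(list(params), pt))
    g <- do.call(purrr::pluck, c(list(an$grads), pt))
    for (i in sample(length(leaf), 3)) {
      nudge <- function(delta) {
        leaf2 <- leaf
        leaf2[i] <- leaf2[i] + delta
        purrr::assign_in(params, pt, leaf2)
      }
      num <- (lossf(nudge(eps)) - lossf(nudge(-eps))) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-4)
    }
  }
})
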