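# Cross-view predictive loss, classifier head and cross-entropy.

# Independent oracle: explicit per-timestep, per-sample softmax loops.
crossview_oracle <- function(c_a, z_b, W) {
  m <- nrow(c_a); n <- dim(z_b)[2]
  total <- 0
  for (t in seq_len(n)) {
    Wt <- if (length(W) == 1) W[[1]] else W[[t]]
    for (i in seq_len(m)) {
      pred <- as.vector(Wt %*% c_a[i, ])
      scores <- sapply(seq_len(m), function(j) sum(pred * z_b[j, t, ]))
      p <- exp(scores - max(scores)); p <- p / sum(p)
      total <- total - log(p[i]) / (n * m)
    }
  }
  total
}

test_that("cross-view loss closed forms: single sample, uniform logits, limits", {
  # m = 1: softmax over one logit is 1, loss exactly 0
  expect_equal(crossview_loss(matrix(rnorm(3), 1, 3),
                              array(rnorm(6), c(1, 2, 3)),
                              list(diag(3), diag(3))), 0)
  # m = 2, uniform scores: log(2)
  expect_equal(crossview_loss(matrix(0, 2, 3), array(0, c(2, 1, 3)),
                              list(diag(3))), log(2), tolerance = 1e-6)
  # strong matched scores drive the loss toward 0
  ca <- matrix(c(30, 0, 0, 30), 2, 2)
  zb <- array(0, c(2, 1, 2)); zb[1, 1, ] <- c(30, 0); zb[2, 1, ] <- c(0, 30)
  expect_lt(crossview_loss(ca, zb, list(diag(2))), 1e-6)
})

test_that("cross-view loss equals the brute-force double-loop oracle", {
  set.seed(19)
  for (rep in 1:10) {
    m <- sample(2:4, 1); n <- sample(1:6, 1); d <- sample(2:8, 1)
    c_a <- matrix(rnorm(m * d), m, d)
    z_b <- array(rnorm(m * n * d), c(m, n, d))
    W <- lapply(seq_len(n), function(t) matrix(rnorm(d * d), d, d))
    got <- crossview_loss(c_a, z_b, W)
    expect_equal(got, crossview_oracle(c_a, z_b, W), tolerance = 1e-6)
    expect_gte(got, 0)
  }
})

test_that("cross-view loss is invariant to a joint batch permutation", {
  set.seed(23)
  m <- 4; n <- 3; d <- 5
  c_a <- matrix(rnorm(m * d), m, d)
  z_b <- array(rnorm(m * n * d), c(m, n, d))
  W <- lapply(seq_len(n), function(t) matrix(rnorm(d * d), d, d))
  perm <- sample(m)
  expect_equal(crossview_loss(c_a, z_b, W),
               crossview_loss(c_a[perm, ], z_b[perm, , , drop = FALSE], W),
               tolerance = 1e-10)
})

test_that("the total loss is the exact sum over ordered view pairs", {
  set.seed(29)
  m <- 3; n <- 2; d <- 4
  mk_view <- function() list(c = matrix(rnorm(m * d), m, d),
                             z = array(rnorm(m * n * d), c(m, n, d)))
  enc <- list(c2v = mk_view(), eiip = mk_view())
  heads <- list(
    "c2v->eiip" = lapply(1:n, function(t) matrix(rnorm(d * d), d, d)),
    "eiip->c2v" = lapply(1:n, function(t) matrix(rnorm(d * d), d, d)))
  pairs <- list(c("c2v", "eiip"), c("eiip", "c2v"))
  expect_equal(total_ssl_loss(enc, heads, pairs),
               crossview_loss(enc$c2v$c, enc$eiip$z, heads[["c2v->eiip"]]) +
                 crossview_loss(enc$eiip$c, enc$c2v$z, heads[["eiip->c2v"]]))
  # all-pairs mode over three views: six terms
  enc3 <- list(knfp = mk_view(), c2v = mk_view(), eiip = mk_view())
  vs <- names(enc3)
  heads3 <- list()
  total <- 0
  for (a in vs) for (b in setdiff(vs, a)) {
    heads3[[paste0(a, "->", b)]] <- lapply(1:n, function(t) diag(d))
    total <- total + crossview_loss(enc3[[a]]$c, enc3[[b]]$z,
                                    heads3[[paste0(a, "->", b)]])
  }
  expect_equal(length(heads3), 6)
  expect_equal(total_ssl_loss(enc3, heads3), total, tolerance = 1e-10)
  expect_error(total_ssl_loss(enc3["c2v"], heads3), "two views")
})

test_that("classifier head produces normalized two-class probabilities", {
  set.seed(31)
  d <- 6
  # zero first layer: logits reduce to b2, so probabilities are hand-checkable
  head0 <- list(W1 = matrix(0, d, 4), b1 = rep(0, 4),
                W2 = matrix(0, 4, 2), b2 = c(0, 0))
  expect_equal(classify(matrix(rnorm(2 * d), 2, d), head0),
               matrix(0.5, 2, 2), tolerance = 1e-12)
  head0$b2 <- c(1, 1 + log(3))
  expect_equal(classify(matrix(rnorm(2 * d), 2, d), head0)[1, ],
               c(0.25, 0.75), tolerance = 1e-10)
  head1 <- list(W1 = matrix(rnorm(d * 4), d, 4), b1 = rnorm(4),
                W2 = matrix(rnorm(8), 4, 2), b2 = rnorm(2))
  p <- classify(matrix(rnorm(5 * d), 5, d), head1)
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
})

test_that("cross-entropy matches hand values and a per-sample loop", {
  expect_lt(cross_entropy(c(1, 0), c(1, 0)), 1e-10)
  expect_equal(cross_entropy(1, 0.5), log(2), tolerance = 1e-12)
  expect_equal(cross_entropy(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-12)
  set.seed(37)
  y <- rbinom(20, 1, 0.5)
  p <- runif(20, 0.01, 0.99)
  oracle <- -mean(sapply(seq_along(y), function(i) {
    if (y[i] == 1) log(p[i]) else log(1 - p[i])
  }))
  expect_equal(cross_entropy(y, p), oracle, tolerance = 1e-10)
  expect_error(cross_entropy(c(1, 0), 0.5), "length")
})
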