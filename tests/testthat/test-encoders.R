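# KNFP, EIIP and PSTNPss encoders.

# Independent oracle: count k-tuples by explicit substring enumeration and
# place each position's tuple frequency in its column.
knfp_oracle_block <- function(seq, k) {
  L <- nchar(seq)
  n <- L - k + 1
  tuples <- substring(seq, 1:n, k:L)
  cols <- sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), k)),
                     1, paste0, collapse = ""))
  # lexicographic order of expand.grid differs; build the A<C<G<T positional code
  code <- function(tu) {
    digits <- match(strsplit(tu, "")[[1]], c("A", "C", "G", "T")) - 1
    sum(digits * 4^((k - 1):0)) + 1
  }
  M <- matrix(0, n, 4^k)
  for (t in seq_len(n)) {
    tu <- tuples[t]
    if (grepl("^[ACGT]+$", tu)) {
      M[t, code(tu)] <- sum(tuples == tu) / n
    }
  }
  M
}

test_that("KNFP blocks match the brute-force counting oracle on random sequences", {
  set.seed(11)
  for (rep in 1:20) {
    s <- random_seq(sample(20:60, 1))
    for (k in 1:3) {
      expect_equal(unname(knfp_block(s, k)), knfp_oracle_block(s, k),
                   tolerance = 1e-12)
    }
  }
})

test_that("KNFP hand examples: homopolymer, ACGT mono- and dinucleotides", {
  f1 <- knfp_block("AAAAA", 1)
  expect_equal(f1[, "A"], rep(1, 5))
  expect_equal(rowSums(f1), rep(1, 5))

  f2 <- knfp_block("ACGT", 1)
  expect_equal(diag(f2[, c("A", "C", "G", "T")]), rep(0.25, 4))

  f3 <- knfp_block("ACGT", 2)
  expect_equal(f3[cbind(1:3, match(c("AC", "CG", "GT"), colnames(f3)))],
               rep(1 / 3, 3))
  expect_equal(sum(f3 != 0), 3)
})

test_that("KNFP shapes and padding follow (L - k + 1, 4^k) with zeros at the end", {
  s <- random_seq(101)
  expect_equal(dim(knfp_block(s, 3)), c(99, 64))
  enc <- knfp_encode(s, kmax = 3)
  expect_equal(dim(enc$matrix), c(101, 84))
  expect_equal(enc$valid_len, 101L)
  # k=2 block: last row zero; k=3 block: last two rows zero
  expect_true(all(enc$matrix[101, 5:20] == 0))
  expect_true(all(enc$matrix[100:101, 21:84] == 0))
})

test_that("distinct observed k-tuple frequencies sum to 1 for each k", {
  set.seed(5)
  for (rep in 1:10) {
    s <- random_seq(101)
    for (k in 1:3) {
      B <- knfp_block(s, k)
      freqs <- apply(B, 2, max)   # each tuple's frequency, 0 if absent
      expect_equal(sum(freqs), 1, tolerance = 1e-12)
    }
  }
})

test_that("KNFP is a per-sequence computation, invariant to batch order", {
  d <- tiny_dataset(n = 10)
  emb <- tiny_embedding(d)
  st1 <- encode_views(d, emb)
  st2 <- encode_views(d[rev(seq_len(nrow(d))), ], emb)
  i <- 3L  # record i in d is record (N - i + 1) in the reversed batch
  rows1 <- ((i - 1) * st1$L + 1):(i * st1$L)
  j <- nrow(d) - i + 1L
  rows2 <- ((j - 1) * st2$L + 1):(j * st2$L)
  expect_equal(st1$knfp[rows1, ], st2$knfp[rows2, ])
})

test_that("ambiguous bases encode to zero rows for the affected tuples", {
  enc <- knfp_encode("ACGTN", kmax = 3)
  expect_true(all(enc$matrix[5, 1:4] == 0))        # N itself, k=1
  expect_true(all(enc$matrix[4:5, 5:20] == 0))     # dinucleotides touching N
  expect_error(knfp_encode("AC", kmax = 3), "kmax")
})

test_that("EIIP reproduces the published constants exactly", {
  expect_identical(unname(eiip_values()[c("G", "C", "T", "A")]),
                   c(0.0806, 0.1340, 0.1335, 0.1260))
  expect_equal(unname(eiip_encode("GCTA")$matrix[, 1]),
               c(0.0806, 0.1340, 0.1335, 0.1260))
  expect_equal(unname(eiip_encode("A")$matrix[, 1]), 0.1260)
})

test_that("EIIP output values come only from the constant set (with 0 for N)", {
  set.seed(3)
  s <- paste0(sample(c("A", "C", "G", "T", "N"), 200, replace = TRUE),
              collapse = "")
  vals <- eiip_encode(s)$matrix[, 1]
  expect_true(all(vals %in% c(0, 0.0806, 0.1340, 0.1335, 0.1260)))
  expect_equal(eiip_encode(s)$valid_len, 200L)
})

test_that("U-containing input encodes as T after ingest normalization", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">u", "U"), fa)
  r <- read_fasta(fa)
  expect_equal(unname(eiip_encode(r$seq)$matrix[1, 1]), 0.1335)
})

test_that("PSTNPss propensities are positive minus negative class frequencies", {
  L <- 10
  pos <- tibble::tibble(id = paste0("p", 1:4), seq = rep(strrep("A", L), 4))
  neg <- tibble::tibble(id = paste0("n", 1:4), seq = rep(strrep("C", L), 4))
  tab <- pstnpss_fit(pos, neg)
  expect_equal(dim(tab), c(64, L - 2))
  expect_true(all(tab["AAA", ] == 1))
  expect_true(all(tab["CCC", ] == -1))
  expect_true(all(tab >= -1 & tab <= 1))
  enc <- pstnpss_encode(strrep("A", L), tab)
  expect_equal(enc[1:(L - 2)], rep(1, L - 2))
  expect_equal(enc[(L - 1):L], c(0, 0))
})

test_that("identical classes give an all-zero propensity table", {
  d <- tiny_dataset(n = 10)
  same <- dplyr::mutate(d, label = NULL)
  tab <- pstnpss_fit(same, same)
  expect_true(all(tab == 0))
  expect_true(all(colSums(tab) == 0))
})

test_that("PSTNPss handles ambiguous bases and validates inputs", {
  pos <- tibble::tibble(id = "p", seq = "AAAAA")
  neg <- tibble::tibble(id = "n", seq = "CCCCC")
  tab <- pstnpss_fit(pos, neg)
  enc <- pstnpss_encode("AAANA", tab)
  expect_equal(enc, c(1, 0, 0, 0, 0))  # trinucleotides touching N are 0
  expect_error(pstnpss_fit(pos[0, ], neg), "non-empty")
  expect_error(pstnpss_encode("AAAA", tab), "length")
})

test_that("EIIP view gains exactly one channel when PSTNPss is enabled", {
  pos <- tibble::tibble(id = "p", seq = "AAAAA")
  neg <- tibble::tibble(id = "n", seq = "CCCCC")
  tab <- pstnpss_fit(pos, neg)
  expect_equal(ncol(eiip_encode("AAAAA")$matrix), 1)
  expect_equal(ncol(eiip_encode("AAAAA", pstnpss = tab)$matrix), 2)
})
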