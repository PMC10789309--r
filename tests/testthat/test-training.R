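# Pretraining and fine-tuning loops on small fixtures.

make_training_setup <- function(n = 40, seed = 3) {
  d <- tiny_dataset(n = n, seed = seed)
  emb <- tiny_embedding(d)
  list(data = d, emb = emb, stacks = encode_views(d, emb))
}

test_that("pretraining reduces the cross-view loss and records a finite curve", {
  setup <- make_training_setup(n = 40)
  ck <- pretrain_crossview(setup$stacks, spec = tiny_spec(dropout = 0.1),
                           tspec = train_spec(epochs = 5, batch_size = 8,
                                              seed = 1))
  lc <- tidy(ck)
  expect_true(all(is.finite(lc$loss)))
  expect_lt(lc$loss[nrow(lc)], lc$loss[1])
})

test_that("pretraining is deterministic for a fixed seed", {
  setup <- make_training_setup(n = 24)
  run <- function() {
    pretrain_crossview(setup$stacks, spec = tiny_spec(dropout = 0.1),
                       tspec = train_spec(epochs = 2, batch_size = 8, seed = 7))
  }
  a <- run(); b <- run()
  expect_identical(tidy(a)$loss, tidy(b)$loss)
  expect_identical(a$params$tf$layers[[1]]$Wq, b$params$tf$layers[[1]]$Wq)
  expect_identical(a$params$heads[[1]][[2]], b$params$heads[[1]][[2]])
})

test_that("a batch size above the dataset size trains as one batch per epoch", {
  setup <- make_training_setup(n = 12)
  ck <- pretrain_crossview(setup$stacks, spec = tiny_spec(),
                           tspec = train_spec(epochs = 2, batch_size = 500,
                                              seed = 2))
  expect_equal(nrow(tidy(ck)), 2)
})

test_that("pretraining never touches labels", {
  d <- tiny_dataset(n = 16)
  unlabeled <- d[, c("id", "seq")]       # no label column at all
  emb <- tiny_embedding(unlabeled)
  ck <- pretrain_crossview(unlabeled, embedding = emb, spec = tiny_spec(),
                           tspec = train_spec(epochs = 1, batch_size = 8,
                                              seed = 1))
  expect_s3_class(ck, "ssl_checkpoint")
})

test_that("all-pairs mode pretrains three views with six prediction heads", {
  setup <- make_training_setup(n = 16)
  ck <- pretrain_crossview(setup$stacks, spec = tiny_spec(),
                           tspec = train_spec(epochs = 1, batch_size = 8,
                                              seed = 1, view_pairs = "all"))
  expect_setequal(ck$views, c("knfp", "c2v", "eiip"))
  expect_length(ck$pairs, 6)
})

test_that("loss decreases over epochs across almost all seeds", {
  setup <- make_training_setup(n = 32)
  wins <- 0
  for (sd in 1:10) {
    ck <- pretrain_crossview(setup$stacks, spec = tiny_spec(dropout = 0),
                             tspec = train_spec(epochs = 3, batch_size = 8,
                                                seed = sd))
    lc <- tidy(ck)
    wins <- wins + (lc$loss[nrow(lc)] < lc$loss[1])
  }
  expect_gte(wins, 9)
})

test_that("fine-tuning decreases training loss and is deterministic", {
  setup <- make_training_setup(n = 40)
  run <- function() {
    finetune(setup$data, ckpt = NULL, embedding = setup$emb,
             spec = tiny_spec(dropout = 0.1),
             tspec = train_spec(epochs = 6, batch_size = 16, seed = 5))
  }
  f1 <- run()
  lc <- tidy(f1)
  expect_lt(lc$loss[nrow(lc)], lc$loss[1])
  f2 <- run()
  expect_identical(f1$params$proj$W2, f2$params$proj$W2)
  expect_identical(f1$params$enc$blocks[[1]]$W, f2$params$enc$blocks[[1]]$W)
})

test_that("warm start, ablation and frozen-transformer paths all run", {
  setup <- make_training_setup(n = 24)
  ck <- pretrain_crossview(setup$stacks, spec = tiny_spec(),
                           tspec = train_spec(epochs = 1, batch_size = 8,
                                              seed = 1))
  ft_warm <- finetune(setup$data, ckpt = ck, embedding = setup$emb,
                      tspec = train_spec(epochs = 2, batch_size = 8, seed = 2))
  expect_true(ft_warm$pretrained)
  ft_cold <- finetune(setup$data, ckpt = NULL, embedding = setup$emb,
                      spec = tiny_spec(),
                      tspec = train_spec(epochs = 2, batch_size = 8, seed = 2))
  expect_false(ft_cold$pretrained)
  ft_frozen <- finetune(setup$data, ckpt = ck, embedding = setup$emb,
                        tspec = train_spec(epochs = 2, batch_size = 8, seed = 2),
                        freeze_transformer = TRUE)
  # frozen transformer parameters stay exactly at the checkpoint values
  expect_identical(ft_frozen$params$tf, ck$params$tf)
  expect_false(identical(ft_warm$params$tf, ck$params$tf))
})

test_that("single-class training sets are rejected", {
  setup <- make_training_setup(n = 16)
  pos_only <- setup$data[setup$data$label == 1, ]
  expect_error(finetune(pos_only, embedding = setup$emb, spec = tiny_spec()),
               "both classes")
})

test_that("fused widths follow the channel arithmetic of the three views", {
  s <- strrep("ACGT", 26)
  s <- substr(paste0(s, "A"), 1, 101)
  emb <- tiny_embedding(tiny_dataset(n = 6), dim = 30)
  v_knfp <- knfp_encode(s)
  v_c2v <- circrna2vec_encode(s, emb)
  v_eiip <- eiip_encode(s)
  fused <- fuse_views(list(v_eiip, v_knfp, v_c2v))   # any order in
  expect_equal(ncol(fused$matrix), 84 + 30 + 1)
  # fixed order out: KNFP block first
  expect_equal(fused$matrix[, 1:84], v_knfp$matrix)
  # PSTNPss adds one channel
  pos <- tibble::tibble(id = "p", seq = strrep("A", 101))
  neg <- tibble::tibble(id = "n", seq = strrep("C", 101))
  tab <- pstnpss_fit(pos, neg)
  fused2 <- fuse_views(list(v_knfp, v_c2v, eiip_encode(s, pstnpss = tab)))
  expect_equal(ncol(fused2$matrix), 116)
  # dropping a view shrinks the width and keeps the remaining order
  fused3 <- fuse_views(list(v_c2v, v_knfp))
  expect_equal(ncol(fused3$matrix), 114)
  expect_equal(fused3$matrix[, 1:84], v_knfp$matrix)
  # mismatched lengths are rejected
  short <- knfp_encode(strrep("ACGT", 10))
  expect_error(fuse_views(list(short, v_c2v)), "identical L")
})

test_that("prediction output is tidy and thresholded at one half", {
  setup <- make_training_setup(n = 24)
  f <- finetune(setup$data, embedding = setup$emb, spec = tiny_spec(),
                tspec = train_spec(epochs = 2, batch_size = 8, seed = 3))
  pr <- predict(f, setup$data)
  expect_s3_class(pr, "tbl_df")
  expect_named(pr, c("id", "p_bound", "pred"))
  expect_true(all(pr$p_bound >= 0 & pr$p_bound <= 1))
  expect_equal(pr$pred, as.integer(pr$p_bound >= 0.5))
  met <- evaluate(f, setup$data)
  expect_true(all(c("auc", "acc", "precision", "recall") %in% names(met)))
})
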