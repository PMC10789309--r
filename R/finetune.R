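# Supervised fine-tuning: the three views are channel-concatenated, passed
# through a fresh conv encoder (its input width differs from the per-view
# pretraining encoders, so it cannot be warm-started), the transformer is
# warm-started from the self-supervised checkpoint (or freshly initialized in
# the ablation arm), and a two-layer projection head is trained with binary
# cross-entropy on the small labeled subset.

# Warm-start the first fused conv block from the pretrained per-view
# encoders. The fused input is the channel concatenation of the views, and a
# convolution is linear in its input channels, so copying each view's first
# conv-block weights into that view's channel rows makes the fused conv equal
# the sum of the pretrained per-view convolutions (channels the checkpoint
# never saw, e.g. the PSTNPss channel, start at zero; normalization scales
# start fresh). This keeps the warm-started transformer's input in the
# feature basis it was pretrained on.
warm_start_fused_encoder <- function(enc, ckpt, spans, spec) {
  K <- spec$conv_kernel
  c_in <- nrow(enc$blocks[[1]]$W) / K
  W <- enc$blocks[[1]]$W * 0
  b <- enc$blocks[[1]]$b * 0
  for (v in names(spans)) {
    if (is.null(ckpt$params$enc[[v]])) next
    Wv <- ckpt$params$enc[[v]]$blocks[[1]]$W
    dv <- nrow(Wv) / K
    cols <- spans[[v]][seq_len(dv)]      # extra channels (PSTNPss) stay zero
    for (j in seq_len(K)) {
      W[(j - 1) * c_in + cols, ] <- Wv[((j - 1) * dv + 1):(j * dv), , drop = FALSE]
    }
    b <- b + ckpt$params$enc[[v]]$blocks[[1]]$b
  }
  # views without a pretrained encoder (e.g. KNFP under the two-view
  # objective) keep their fresh random rows
  untouched <- setdiff(names(spans),
                       intersect(names(spans), names(ckpt$params$enc)))
  for (v in untouched) {
    cols <- spans[[v]]
    for (j in seq_len(K)) {
      rows <- (j - 1) * c_in + cols
      W[rows, ] <- enc$blocks[[1]]$W[rows, , drop = FALSE]
    }
  }
  enc$blocks[[1]]$W <- W
  enc$blocks[[1]]$b <- b
  enc
}

# Loss and gradients of one fine-tuning mini-batch. `tf_p` carries the
# transformer parameters actually used in the forward pass (either the
# trainable copy or the frozen checkpoint parameters). Shared by the training
# loop and the finite-difference gradient checks.
ft_batch_grad <- function(params, tf_p, Xb, yb, m, L, n, spec, train = TRUE,
                          want_grad = TRUE, vd = NULL) {
  if (train && !is.null(vd) && vd$p > 0) {
    # View-level (modality) dropout: zero a whole view's channel block per
    # sample with probability p, rescaling kept blocks by 1/(1-p). Keeps the
    # classifier from leaning on any single view (in particular, on the
    # near-unique k-mer embedding signatures of individual fragments).
    keep <- matrix(stats::runif(m * length(vd$spans)) >= vd$p, m)
    keep[rowSums(keep) == 0, ] <- TRUE      # never drop every view at once
    Xb <- Xb  # local copy
    for (i in seq_len(m)) {
      rows <- ((i - 1L) * L + 1L):(i * L)
      for (v in seq_along(vd$spans)) {
        cols <- vd$spans[[v]]
        Xb[rows, cols] <- if (keep[i, v]) {
          Xb[rows, cols] / (1 - vd$p)
        } else {
          0
        }
      }
    }
  }
  cf <- conv_encoder_fwd(Xb, m, L, params$enc, spec)
  tf <- transformer_fwd_int(cf$out, m, n, tf_p, spec, train = train)
  H <- pmax(add_bias(tf$c %*% params$proj$W1, params$proj$b1), 0)
  logits <- add_bias(H %*% params$proj$W2, params$proj$b2)
  probs <- row_softmax(logits)
  loss <- cross_entropy(yb, probs[, 2L])
  if (!want_grad) return(list(loss = loss, probs = probs))
  Yhot <- cbind(1 - yb, yb)
  dlogits <- (probs - Yhot) / m
  gproj <- list(W1 = NULL, b1 = NULL, W2 = crossprod(H, dlogits),
                b2 = colSums(dlogits))
  dH <- tcrossprod(dlogits, params$proj$W2) * (H > 0)
  gproj$W1 <- crossprod(tf$c, dH)
  gproj$b1 <- colSums(dH)
  dC <- tcrossprod(dH, params$proj$W1)
  tb <- transformer_bwd_int(dC, NULL, tf, m, n, tf_p, spec)
  cb <- conv_encoder_bwd(tb$dZ, cf, params$enc, spec, m, L)
  list(loss = loss, probs = probs,
       grads = list(enc = cb$grads, proj = gproj), gtf = tb$grads)
}

#' Fine-tune a binding-site classifier from a small labeled set
#'
#' @param train Tibble of labeled sequence records (both classes present).
#' @param ckpt An [pretrain_crossview()] checkpoint to warm-start the
#'   transformer, or `NULL` for the no-pretraining ablation (identical code
#'   path, randomly initialized transformer).
#' @param embedding Trained [train_embedding()] model.
#' @param spec A [model_spec()]; defaults to the checkpoint's spec.
#' @param tspec A [train_spec()]; defaults to 100 epochs with early stopping
#'   (patience 10) on the training loss.
#' @param pstnpss Append the position-specific trinucleotide propensity
#'   channel, fitted on `train` only (default `TRUE`).
#' @param warm_start_encoder When a checkpoint is given, initialize the first
#'   fused conv block from the pretrained per-view encoders (a convolution is
#'   linear in its input channels, so the per-view kernels embed exactly into
#'   the corresponding channel rows of the fused kernel); channels the
#'   checkpoint never saw start at zero. Keeps the warm-started transformer's
#'   input in the feature basis it was pretrained on. Default `TRUE`.
#' @param view_dropout Probability of zeroing a whole view's channel block
#'   per sample during training (modality dropout; kept blocks are rescaled
#'   by `1/(1-p)`). Regularizes against single-view shortcuts such as
#'   memorizing per-fragment embedding signatures. Default 0.3; 0 disables.
#' @param freeze_transformer Keep the warm-started transformer fixed and train
#'   only the fused encoder and projection head (default `FALSE`).
#' @param stacks,stack_index Optional precomputed [encode_views()] stacks for
#'   a superset dataset and the row positions of `train` within it (avoids
#'   re-encoding in sweeps).
#' @return An `rbp_classifier` with trained parameters, loss curve and the
#'   fitted PSTNPss table.
#' @export
finetune <- function(train, ckpt = NULL, embedding = NULL, spec = NULL,
                     tspec = train_spec(epochs = 100, early_stop = 10),
                     pstnpss = TRUE, view_dropout = 0.3,
                     warm_start_encoder = TRUE, freeze_transformer = FALSE,
                     stacks = NULL, stack_index = NULL) {
  assert_records(train, "train")
  y <- train$label
  if (any(is.na(y)) || length(unique(y)) < 2L) {
    stop("training set must contain both classes with no missing labels",
         call. = FALSE)
  }
  spec <- spec %||% (if (!is.null(ckpt)) ckpt$model_spec else model_spec_compact())
  if (!is.null(ckpt) && !identical(unclass(spec), unclass(ckpt$model_spec))) {
    stop("model spec does not match the checkpoint", call. = FALSE)
  }

  if (is.null(stacks)) {
    if (is.null(embedding)) stop("embedding model required", call. = FALSE)
    stacks <- encode_views(train, embedding)
    stack_index <- seq_len(nrow(train))
  }
  L <- stacks$L
  n <- L %/% spec$pool
  if (!is.null(ckpt) && ckpt$n != n) {
    stop("encoded length differs from the checkpoint", call. = FALSE)
  }

  ptab <- NULL
  pcol <- NULL
  if (pstnpss) {
    ptab <- pstnpss_fit(train[train$label == 1L, ], train[train$label == 0L, ])
    pcol <- unlist(lapply(train$seq, pstnpss_encode, table = ptab))
  }
  X <- fused_stack(stacks, stack_index, pcol)
  N <- nrow(train)
  d_k <- unname(stacks$dims["knfp"])
  d_c <- unname(stacks$dims["c2v"])
  d_e <- ncol(X) - d_k - d_c            # EIIP plus any PSTNPss channel
  spans <- list(knfp = seq_len(d_k), c2v = d_k + seq_len(d_c),
                eiip = d_k + d_c + seq_len(d_e))
  vd <- if (view_dropout > 0) list(p = view_dropout, spans = spans)

  local_seed(tspec$seed, {
    tf0 <- if (!is.null(ckpt)) ckpt$params$tf else init_transformer(spec, n)
    params <- list(enc = init_conv_encoder(ncol(X), spec),
                   proj = init_projection_head(spec$dim, spec$mlp_dim))
    if (!is.null(ckpt) && warm_start_encoder) {
      params$enc <- warm_start_fused_encoder(params$enc, ckpt, spans, spec)
    }
    if (!freeze_transformer) params$tf <- tf0
    opt <- adam_init(params)
    sched <- plateau_init(tspec)
    curve <- vector("list", tspec$epochs)

    for (ep in seq_len(tspec$epochs)) {
      order <- sample.int(N)
      starts <- seq(1L, N, by = tspec$batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- order[s:min(s + tspec$batch_size - 1L, N)]
        m <- length(idx)
        rows <- stack_index_rows(idx, L)
        tf_p <- if (freeze_transformer) tf0 else params$tf
        bg <- ft_batch_grad(params, tf_p, X[rows, , drop = FALSE], y[idx],
                            m, L, n, spec, vd = vd)
        loss <- bg$loss
        if (!is.finite(loss)) {
          stop(sprintf("fine-tuning diverged (non-finite loss, epoch %d)", ep),
               call. = FALSE)
        }
        grads <- bg$grads
        if (!freeze_transformer) grads$tf <- bg$gtf
        st <- adam_step(params, grads, opt, sched$lr, tspec)
        params <- st$params
        opt <- st$state
        ep_loss <- ep_loss + loss * m
      }
      ep_loss <- ep_loss / N
      curve[[ep]] <- tibble::tibble(epoch = ep, loss = ep_loss, lr = sched$lr)
      sched <- plateau_update(sched, ep_loss, tspec)
      if (sched$stop) break
    }

    if (freeze_transformer) params$tf <- tf0
    structure(list(params = params, model_spec = spec, train_spec = tspec,
                   loss_curve = dplyr::bind_rows(curve),
                   pstnpss_table = ptab, embedding = embedding,
                   view_dropout = view_dropout,
                   pretrained = !is.null(ckpt),
                   freeze_transformer = freeze_transformer,
                   L = L, n = n, n_train = N,
                   n_params = tree_param_count(params)),
              class = "rbp_classifier")
  })
}

#' @export
print.rbp_classifier <- function(x, ...) {
  lc <- x$loss_curve
  cat(sprintf(
    "<rbp_classifier> %s transformer | %d labeled samples | %d epochs, loss %.4f -> %.4f\n",
    if (x$pretrained) "pretrained" else "fresh", x$n_train, nrow(lc),
    lc$loss[1], lc$loss[nrow(lc)]))
  invisible(x)
}

#' Predict binding probabilities for new fragments
#'
#' @param object An [finetune()] classifier.
#' @param newdata Tibble of sequence records.
#' @param stacks,stack_index Optional precomputed [encode_views()] stacks and
#'   row positions of `newdata` in them.
#' @param batch_size Forward-pass batch size.
#' @param ... Unused.
#' @return Tibble with `id`, `p_bound` (probability of the positive class)
#'   and `pred` at threshold 0.5.
#' @export
predict.rbp_classifier <- function(object, newdata, stacks = NULL,
                                   stack_index = NULL, batch_size = 256, ...) {
  assert_records(newdata, "newdata")
  if (is.null(stacks)) {
    stacks <- encode_views(newdata, object$embedding)
    stack_index <- seq_len(nrow(newdata))
  }
  pcol <- NULL
  if (!is.null(object$pstnpss_table)) {
    pcol <- unlist(lapply(newdata$seq, pstnpss_encode,
                          table = object$pstnpss_table))
  }
  X <- fused_stack(stacks, stack_index, pcol)
  L <- object$L
  n <- object$n
  spec <- object$model_spec
  N <- nrow(newdata)
  p1 <- numeric(N)
  for (s in seq(1L, N, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, N)
    rows <- stack_index_rows(idx, L)
    cf <- conv_encoder_fwd(X[rows, , drop = FALSE], length(idx), L,
                           object$params$enc, spec)
    tf <- transformer_fwd_int(cf$out, length(idx), n, object$params$tf, spec,
                              train = FALSE)
    p1[idx] <- classify(tf$c, object$params$proj)[, 2L]
  }
  tibble::tibble(id = newdata$id, p_bound = p1, pred = as.integer(p1 >= 0.5))
}

#' Classification metrics from scores and labels
#'
#' AUC is computed from the rank (Mann-Whitney) statistic of the positive-
#' class scores; accuracy, precision and recall use the given threshold.
#' With a single-class label vector the AUC is undefined and reported as `NA`
#' with a warning.
#'
#' @param scores Predicted positive-class probabilities.
#' @param labels Binary labels.
#' @param threshold Decision threshold (default 0.5).
#' @return One-row tibble: `auc`, `acc`, `precision`, `recall`, `n_test`,
#'   `threshold`.
#' @export
metrics_report <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1L
  auc <- if (!any(pos) || all(pos)) {
    warning("AUC undefined for a single-class test set")
    NA_real_
  } else {
    r <- rank(scores)
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  }
  pred <- scores >= threshold
  acc <- mean(pred == pos)
  precision <- if (any(pred)) mean(pos[pred]) else 0
  recall <- if (any(pos)) mean(pred[pos]) else 0
  tibble::tibble(auc = auc, acc = acc, precision = precision, recall = recall,
                 n_test = length(labels), threshold = threshold)
}

#' Evaluate a fitted classifier on labeled test records
#'
#' @param fitted An [finetune()] classifier.
#' @param test Labeled tibble of sequence records.
#' @param stacks,stack_index Optional precomputed stacks (see
#'   [predict.rbp_classifier()]).
#' @param threshold Decision threshold.
#' @return One-row metrics tibble (see [metrics_report()]).
#' @export
evaluate <- function(fitted, test, stacks = NULL, stack_index = NULL,
                     threshold = 0.5) {
  stopifnot(inherits(fitted, "rbp_classifier"))
  if (nrow(test) == 0L) stop("empty test set", call. = FALSE)
  pr <- predict(fitted, test, stacks = stacks, stack_index = stack_index)
  metrics_report(pr$p_bound, test$label, threshold)
}
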