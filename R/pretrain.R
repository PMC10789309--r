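# Self-supervised cross-view pretraining: per-view conv encoders and a shared
# transformer are trained so each view's context vector predicts the other
# view's per-position encodings against in-batch negatives. No labels are
# touched at any point in this stage.

ssl_views_for <- function(view_pairs) {
  if (view_pairs == "all") c("knfp", "c2v", "eiip") else c("c2v", "eiip")
}

ssl_pairs_for <- function(view_pairs) {
  vs <- ssl_views_for(view_pairs)
  g <- expand.grid(from = vs, to = vs, stringsAsFactors = FALSE)
  g <- g[g$from != g$to, ]
  lapply(seq_len(nrow(g)), function(i) c(g$from[i], g$to[i]))
}

# Loss and gradients of one pretraining mini-batch. `Xv` is a named list of
# per-view input slices ((m*L) x D_v). Shared by the training loop and the
# finite-difference gradient checks in the test suite.
ssl_batch_grad <- function(params, Xv, m, L, n, spec, pairs, pair_keys,
                           train = TRUE, want_grad = TRUE) {
  views <- names(Xv)
  fwd <- list()
  for (v in views) {
    cf <- conv_encoder_fwd(Xv[[v]], m, L, params$enc[[v]], spec)
    tf <- transformer_fwd_int(cf$out, m, n, params$tf, spec, train = train)
    fwd[[v]] <- list(conv = cf, tf = tf)
  }
  loss <- 0
  dC <- lapply(fwd, function(f) f$tf$c * 0)
  dZ <- lapply(fwd, function(f) f$conv$out * 0)
  gheads <- stats::setNames(vector("list", length(pairs)), pair_keys)
  for (k in seq_along(pairs)) {
    a <- pairs[[k]][1]; b <- pairs[[k]][2]
    term <- cv_term(fwd[[a]]$tf$c, fwd[[b]]$conv$out, m, n,
                    params$heads[[pair_keys[k]]], want_grad = want_grad)
    loss <- loss + term$loss
    if (want_grad) {
      dC[[a]] <- dC[[a]] + term$dC
      dZ[[b]] <- dZ[[b]] + term$dZ
      gheads[[pair_keys[k]]] <- term$dW
    }
  }
  if (!want_grad) return(list(loss = loss))
  gtf <- NULL
  genc <- stats::setNames(vector("list", length(views)), views)
  for (v in views) {
    tb <- transformer_bwd_int(dC[[v]], NULL, fwd[[v]]$tf, m, n, params$tf, spec)
    gtf <- if (is.null(gtf)) tb$grads else tree_add(gtf, tb$grads)
    cb <- conv_encoder_bwd(tb$dZ + dZ[[v]], fwd[[v]]$conv, params$enc[[v]],
                           spec, m, L)
    genc[[v]] <- cb$grads
  }
  list(loss = loss, grads = list(enc = genc, tf = gtf, heads = gheads))
}

#' Pretrain the feature extractor with cross-view sequence prediction
#'
#' Runs mini-batch Adam on the summed cross-view loss over the configured
#' ordered view pairs (default: embedding predicts EIIP and EIIP predicts the
#' embedding; `view_pairs = "all"` adds the KNFP view and uses all six
#' ordered pairs). Labels are never read. Fully seeded: the same inputs and
#' seed reproduce the same checkpoint.
#'
#' @param x Either a tibble of sequence records or a precomputed
#'   [encode_views()] result.
#' @param embedding Trained [train_embedding()] model (required when `x` is
#'   a record tibble).
#' @param spec A [model_spec()].
#' @param tspec A [train_spec()]; `tspec$view_pairs` selects the pairing.
#' @param shared_head Use one shared prediction map for every timestep
#'   instead of one per timestep (default `FALSE`).
#' @return An `ssl_checkpoint`: trained parameters, specs, the per-epoch loss
#'   curve and bookkeeping (encoded length `n`, parameter count).
#' @export
pretrain_crossview <- function(x, embedding = NULL, spec = model_spec_compact(),
                               tspec = train_spec(), shared_head = FALSE) {
  stacks <- if (inherits(x, "view_stacks")) x else {
    if (is.null(embedding)) stop("embedding model required", call. = FALSE)
    encode_views(x, embedding)
  }
  if (stacks$N < 1L) stop("empty dataset", call. = FALSE)
  views <- ssl_views_for(tspec$view_pairs)
  pairs <- ssl_pairs_for(tspec$view_pairs)
  pair_keys <- vapply(pairs, function(p) paste0(p[1], "->", p[2]), character(1))
  L <- stacks$L
  n <- L %/% spec$pool

  local_seed(tspec$seed, {
    params <- list(
      enc = stats::setNames(
        lapply(views, function(v) init_conv_encoder(ncol(stacks[[v]]), spec)),
        views),
      tf = init_transformer(spec, n),
      heads = init_heads(n, spec$dim, pair_keys, shared = shared_head)
    )
    opt <- adam_init(params)
    sched <- plateau_init(tspec)
    curve <- vector("list", tspec$epochs)

    for (ep in seq_len(tspec$epochs)) {
      order <- sample.int(stacks$N)
      starts <- seq(1L, stacks$N, by = tspec$batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- order[s:min(s + tspec$batch_size - 1L, stacks$N)]
        m <- length(idx)
        rows <- stack_index_rows(idx, L)
        Xv <- stats::setNames(
          lapply(views, function(v) stacks[[v]][rows, , drop = FALSE]), views)
        bg <- ssl_batch_grad(params, Xv, m, L, n, spec, pairs, pair_keys)
        if (!is.finite(bg$loss)) {
          stop(sprintf("pretraining diverged (non-finite loss, epoch %d)", ep),
               call. = FALSE)
        }
        st <- adam_step(params, bg$grads, opt, sched$lr, tspec)
        params <- st$params
        opt <- st$state
        ep_loss <- ep_loss + bg$loss * m
      }
      ep_loss <- ep_loss / stacks$N
      curve[[ep]] <- tibble::tibble(epoch = ep, loss = ep_loss, lr = sched$lr)
      sched <- plateau_update(sched, ep_loss, tspec)
      if (sched$stop) break
    }

    structure(list(params = params, model_spec = spec, train_spec = tspec,
                   loss_curve = dplyr::bind_rows(curve), views = views,
                   pairs = pair_keys, n = n, L = L,
                   shared_head = shared_head,
                   n_params = tree_param_count(params)),
              class = "ssl_checkpoint")
  })
}

#' @export
print.ssl_checkpoint <- function(x, ...) {
  lc <- x$loss_curve
  cat(sprintf(
    "<ssl_checkpoint> views %s | n=%d dim=%d | %d epochs, loss %.4f -> %.4f | %d params\n",
    paste(x$views, collapse = "+"), x$n, x$model_spec$dim, nrow(lc),
    lc$loss[1], lc$loss[nrow(lc)], x$n_params))
  invisible(x)
}
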