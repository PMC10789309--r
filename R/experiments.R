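# End-to-end experiment runners: single pipeline run, training-ratio sweep,
# and the with/without-pretraining ablation.

default_pre_spec <- function(seed) {
  train_spec(epochs = 12, early_stop = 6, seed = seed)
}

default_ft_spec <- function(seed) {
  train_spec(epochs = 15, patience = 3, early_stop = 4, seed = seed)
}

# Embedding settings used by the experiment runners: singletons dropped (the
# view should carry recurring structure, not per-fragment signatures) and a
# small epoch budget.
default_embedding <- function(data, dim, seed) {
  train_embedding(build_corpus(data), dim = dim, epochs = 5, min_count = 2,
                  seed = seed)
}

#' Run the full pipeline once
#'
#' Splits the labeled dataset, trains the k-mer embedding, pretrains the
#' feature extractor on all fragments without labels (the label-efficiency
#' setting: representation learning sees everything, labels only the small
#' training split), fine-tunes on the training split, and evaluates on the
#' held-out split.
#'
#' @param data Labeled tibble of sequence records.
#' @param ratio Train:test ratio, e.g. `c(1, 9)`.
#' @param seed Master seed; stream seeds for the embedding, pretraining and
#'   fine-tuning are derived from it.
#' @param pretrain Run the self-supervised stage (`FALSE` gives the ablation
#'   arm: identical code path, freshly initialized transformer).
#' @param spec A [model_spec()]; default [model_spec_compact()].
#' @param pre_tspec,ft_tspec Optional [train_spec()] overrides for the two
#'   stages (seeds are taken from `seed` unless supplied).
#' @param embed_dim Embedding dimension (default 30).
#' @param embedding,stacks Optional precomputed embedding model and
#'   [encode_views()] stacks for `data` (reused across runs in sweeps).
#' @param corpus Optional unlabeled record tibble for embedding training;
#'   defaults to the dataset's own sequences.
#' @param pstnpss Use the PSTNPss channel at fine-tuning (default `TRUE`).
#' @return A `pipeline_run`: metrics, the fitted classifier, the checkpoint
#'   (or `NULL`), per-record test predictions and run metadata.
#' @export
run_pipeline <- function(data, ratio = c(1, 9), seed = 1, pretrain = TRUE,
                         spec = model_spec_compact(), pre_tspec = NULL,
                         ft_tspec = NULL, embed_dim = 30, embedding = NULL,
                         stacks = NULL, corpus = NULL, pstnpss = TRUE) {
  assert_records(data)
  split <- split_dataset(data, ratio = ratio, seed = seed)
  embedding <- embedding %||% default_embedding(corpus %||% data, embed_dim,
                                                child_seed(seed, 1L))
  stacks <- stacks %||% encode_views(data, embedding)

  ckpt <- NULL
  if (pretrain) {
    ckpt <- pretrain_crossview(stacks, spec = spec,
                               tspec = pre_tspec %||%
                                 default_pre_spec(child_seed(seed, 2L)))
  }

  data_pos <- seq_len(nrow(data))
  names(data_pos) <- data$id
  fitted <- finetune(split$train, ckpt = ckpt, embedding = embedding,
                     spec = spec,
                     tspec = ft_tspec %||% default_ft_spec(child_seed(seed, 3L)),
                     pstnpss = pstnpss, stacks = stacks,
                     stack_index = unname(data_pos[split$train$id]))
  preds <- predict(fitted, split$test, stacks = stacks,
                   stack_index = unname(data_pos[split$test$id]))
  metrics <- metrics_report(preds$p_bound, split$test$label)

  structure(list(metrics = metrics, fitted = fitted, ckpt = ckpt,
                 predictions = dplyr::mutate(preds, label = split$test$label),
                 ratio = ratio, seed = seed, pretrained = pretrain),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf(
    "<pipeline_run> ratio %d:%d seed %s (%s)  AUC %.3f  ACC %.3f  P %.3f  R %.3f\n",
    x$ratio[1], x$ratio[2], format(x$seed),
    if (x$pretrained) "pretrained" else "no pretraining",
    x$metrics$auc, x$metrics$acc, x$metrics$precision, x$metrics$recall))
  invisible(x)
}

#' Training-ratio sweep
#'
#' Fine-tunes at each train:test ratio (default 1:9 through 8:2) from one
#' shared self-supervised checkpoint (pretraining never sees labels, so it is
#' ratio-independent); each ratio reshuffles the split with its own logged
#' seed stream.
#'
#' @inheritParams run_pipeline
#' @param ratios List of length-2 integer vectors; default
#'   `1:9, 2:8, ..., 8:2`.
#' @param ckpt Optional precomputed [pretrain_crossview()] checkpoint.
#' @return A `ratio_sweep` tibble: one row per ratio with the four metrics
#'   and split sizes.
#' @export
ratio_sweep <- function(data, ratios = lapply(1:8, function(k) c(k, 10L - k)),
                        seed = 1, pretrain = TRUE, spec = model_spec_compact(),
                        embed_dim = 30, pstnpss = TRUE, embedding = NULL,
                        stacks = NULL, ckpt = NULL) {
  assert_records(data)
  embedding <- embedding %||% default_embedding(data, embed_dim,
                                                child_seed(seed, 1L))
  stacks <- stacks %||% encode_views(data, embedding)
  if (pretrain && is.null(ckpt)) {
    ckpt <- pretrain_crossview(stacks, spec = spec,
                               tspec = default_pre_spec(child_seed(seed, 2L)))
  }
  if (!pretrain) ckpt <- NULL
  data_pos <- stats::setNames(seq_len(nrow(data)), data$id)

  rows <- lapply(seq_along(ratios), function(k) {
    ratio <- ratios[[k]]
    split <- split_dataset(data, ratio = ratio, seed = child_seed(seed, 100L + k))
    fitted <- finetune(split$train, ckpt = ckpt, embedding = embedding,
                       spec = spec,
                       tspec = default_ft_spec(child_seed(seed, 200L + k)),
                       pstnpss = pstnpss, stacks = stacks,
                       stack_index = unname(data_pos[split$train$id]))
    met <- evaluate(fitted, split$test, stacks = stacks,
                    stack_index = unname(data_pos[split$test$id]))
    dplyr::bind_cols(
      tibble::tibble(ratio = sprintf("%d:%d", ratio[1], ratio[2]),
                     n_train = nrow(split$train)),
      met)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ratio_sweep", class(out))
  out
}

#' With/without-pretraining ablation over seeds
#'
#' For each seed, runs fine-tuning twice on the same split: once warm-started
#' from the self-supervised checkpoint and once from random initialization
#' (identical code path otherwise). The label-free checkpoint, the embedding
#' and the view encodings are computed once and shared across seeds and arms
#' (pretraining sees no labels, so it is not part of the randomness the
#' ablation probes); split and fine-tuning randomness vary with the seed.
#'
#' @inheritParams run_pipeline
#' @param seeds Integer vector of master seeds.
#' @param ckpt Optional precomputed [pretrain_crossview()] checkpoint.
#' @return An `ablation_result` tibble: one row per seed x arm.
#' @export
ablation_run <- function(data, ratio = c(1, 9), seeds = 1:10,
                         spec = model_spec_compact(), embed_dim = 30,
                         pstnpss = TRUE, embedding = NULL, stacks = NULL,
                         ckpt = NULL) {
  assert_records(data)
  base <- seeds[1]
  embedding <- embedding %||% default_embedding(data, embed_dim,
                                                child_seed(base, 1L))
  stacks <- stacks %||% encode_views(data, embedding)
  ckpt <- ckpt %||% pretrain_crossview(
    stacks, spec = spec, tspec = default_pre_spec(child_seed(base, 2L)))
  data_pos <- stats::setNames(seq_len(nrow(data)), data$id)

  rows <- list()
  for (sd in seeds) {
    split <- split_dataset(data, ratio = ratio, seed = sd)
    tr_idx <- unname(data_pos[split$train$id])
    te_idx <- unname(data_pos[split$test$id])
    for (arm in c("pretrained", "scratch")) {
      fitted <- finetune(split$train,
                         ckpt = if (arm == "pretrained") ckpt else NULL,
                         embedding = embedding, spec = spec,
                         tspec = default_ft_spec(child_seed(sd, 3L)),
                         pstnpss = pstnpss, stacks = stacks,
                         stack_index = tr_idx)
      met <- evaluate(fitted, split$test, stacks = stacks,
                      stack_index = te_idx)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(seed = sd, arm = arm), met)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ablation_result", class(out))
  out
}
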