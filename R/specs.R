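#' Transformer feature-extractor architecture settings
#'
#' Defaults follow the reference configuration: one pre-norm transformer layer
#' with width 400, 8 attention heads and a 200-wide feed-forward block, fed by
#' a per-view stack of 1-D convolutions (3 blocks, kernel 8, stride 1, same
#' padding) followed by a width-`pool` max-pool along the position axis, so
#' the encoded length is `n = floor(L / pool)`.
#'
#' @param dim Transformer width (divisible by `heads`).
#' @param heads Number of attention heads.
#' @param mlp_dim Feed-forward hidden width.
#' @param layers Transformer depth.
#' @param dropout Dropout probability inside the feed-forward block.
#' @param conv_blocks Number of convolution + ReLU blocks in the input encoder.
#' @param conv_kernel Convolution kernel width.
#' @param conv_norm Apply a per-position layer norm over channels inside each
#'   conv block (batch-independent, stabilizes the scale of the encoded
#'   features; default `TRUE`).
#' @param pool Max-pool width (= stride) applied after the conv stack.
#' @param context How the whole-sequence context vector is extracted:
#'   `"token"` prepends a learnable context token whose final hidden state is
#'   the context; `"mean"` mean-pools the final hidden states.
#' @param positional Add a learned positional embedding to the encoded
#'   sequence (default `FALSE`; the conv encoder already injects locality).
#' @return A `model_spec` list.
#' @export
model_spec <- function(dim = 400, heads = 8, mlp_dim = 200, layers = 1,
                       dropout = 0.1, conv_blocks = 3, conv_kernel = 8,
                       conv_norm = TRUE, pool = 2,
                       context = c("token", "mean"), positional = FALSE) {
  context <- match.arg(context)
  if (dim %% heads != 0) stop("dim must be divisible by heads", call. = FALSE)
  stopifnot(layers >= 1, dropout >= 0, dropout < 1, conv_blocks >= 1,
            conv_kernel >= 1, pool >= 1)
  structure(list(dim = as.integer(dim), heads = as.integer(heads),
                 mlp_dim = as.integer(mlp_dim), layers = as.integer(layers),
                 dropout = dropout, conv_blocks = as.integer(conv_blocks),
                 conv_kernel = as.integer(conv_kernel),
                 conv_norm = isTRUE(conv_norm), pool = as.integer(pool),
                 context = context, positional = positional),
            class = "model_spec")
}

#' Compact architecture for desk-scale experiments
#'
#' A reduced configuration (width 32, 4 heads, one conv block, pool 4) used by
#' the experiment runners and the test suite so full pretrain + fine-tune
#' cycles complete in seconds-to-minutes on one CPU. The architecture is
#' identical in kind to [model_spec()]; only the sizes shrink.
#'
#' @param ... Overrides passed to [model_spec()].
#' @return A `model_spec` list.
#' @export
model_spec_compact <- function(...) {
  args <- list(dim = 32, heads = 4, mlp_dim = 32, layers = 1, dropout = 0.1,
               conv_blocks = 1, conv_kernel = 8, pool = 4)
  args[names(list(...))] <- list(...)
  do.call(model_spec, args)
}

#' Optimization settings
#'
#' Defaults follow the reference setup: Adam with `beta1 = 0.9`,
#' `beta2 = 0.99`, weight decay `3e-4`, batch size 64 and an initial learning
#' rate of `3e-3` under a reduce-on-plateau schedule (halve when the epoch
#' training loss has not improved for `patience` epochs), plus early stopping
#' after `early_stop` epochs without improvement.
#'
#' @param batch_size Mini-batch size.
#' @param epochs Maximum epochs.
#' @param lr Initial learning rate.
#' @param beta1,beta2 Adam moment decay rates.
#' @param weight_decay L2 weight-decay coefficient added to gradients.
#' @param lr_factor,patience Reduce-on-plateau: multiply `lr` by `lr_factor`
#'   after `patience` epochs without improvement.
#' @param early_stop Stop after this many epochs without improvement
#'   (`Inf` disables).
#' @param min_lr Floor for the scheduled learning rate.
#' @param seed Integer seed covering initialization, shuffling and dropout.
#' @param view_pairs Ordered view pairs for the cross-view loss:
#'   `"eq5"` uses (embedding -> EIIP) and (EIIP -> embedding);
#'   `"all"` uses every ordered pair over the three views.
#' @return A `train_spec` list.
#' @export
train_spec <- function(batch_size = 64, epochs = 40, lr = 3e-3, beta1 = 0.9,
                       beta2 = 0.99, weight_decay = 3e-4, lr_factor = 0.5,
                       patience = 3, early_stop = 8, min_lr = 1e-5, seed = 1,
                       view_pairs = c("eq5", "all")) {
  view_pairs <- match.arg(view_pairs)
  stopifnot(batch_size >= 1, lr > 0, epochs >= 1)
  structure(list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 lr = lr, beta1 = beta1, beta2 = beta2,
                 weight_decay = weight_decay, lr_factor = lr_factor,
                 patience = as.integer(patience), early_stop = early_stop,
                 min_lr = min_lr, seed = seed, view_pairs = view_pairs),
            class = "train_spec")
}
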