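# Shared helpers: tiny seeded datasets and model configs used across tests.

tiny_dataset <- function(n = 60, seed = 3, L = 101) {
  generate_dataset(fixture_config(n = n, L = L, seed = seed))
}

tiny_embedding <- function(records, dim = 8, epochs = 2, seed = 1) {
  train_embedding(build_corpus(records), dim = dim, epochs = epochs, seed = seed)
}

# A very small architecture so forward/backward tests run in milliseconds.
tiny_spec <- function(...) {
  args <- list(dim = 8, heads = 2, mlp_dim = 6, layers = 1, dropout = 0,
               conv_blocks = 1, conv_kernel = 3, pool = 4)
  args[names(list(...))] <- list(...)
  do.call(model_spec, args)
}

random_seq <- function(L) {
  paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# Transformer parameters with all attention and feed-forward weights zeroed
# (layer-norm scales kept): the pre-norm residual path alone.
zeroed_transformer <- function(tf) {
  for (l in seq_along(tf$layers)) {
    for (nm in c("Wq", "Wk", "Wv", "Wo", "W1", "W2")) {
      tf$layers[[l]][[nm]] <- tf$layers[[l]][[nm]] * 0
    }
  }
  tf
}
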