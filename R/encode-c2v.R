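# Paragraph-vector k-mer embedding view. Sequences become "documents" of
# overlapping fixed-width words (default 10-mers); a distributed-memory
# paragraph-vector model (paragraph vector + context word vectors jointly
# predict the centre word, trained with negative sampling) supplies one
# embedding per word, emitted per position so the downstream transformer keeps
# the temporal axis.

#' Turn sequence records into k-mer documents
#'
#' Each sequence of length `L` becomes an ordered document of its
#' `L - word_len + 1` overlapping `word_len`-mers.
#'
#' @param records Tibble of sequence records (or a character vector).
#' @param word_len Sliding-window word size (default 10).
#' @return A named list of character vectors, one document per record.
#' @export
#' @examples
#' build_corpus(tibble::tibble(id = "s", seq = "ACGTACGTACGT"), word_len = 10)
build_corpus <- function(records, word_len = 10) {
  if (is.character(records)) {
    records <- tibble::tibble(id = paste0("doc_", seq_along(records)),
                              seq = records)
  }
  assert_records(records)
  short <- nchar(records$seq) < word_len
  if (any(short)) {
    stop("sequences shorter than word_len: ",
         paste(utils::head(records$id[short], 5L), collapse = ", "),
         call. = FALSE)
  }
  docs <- lapply(records$seq, function(s) {
    n <- nchar(s) - word_len + 1L
    substring(s, seq_len(n), seq_len(n) + word_len - 1L)
  })
  names(docs) <- records$id
  docs
}

#' Train the paragraph-vector embedding
#'
#' Distributed-memory objective: for each centre word, the mean of the
#' surrounding word vectors (window `window` each side) and the document's
#' paragraph vector predicts the centre word against sampled negatives.
#' Single worker and an explicit seed make training exactly reproducible.
#'
#' @param corpus A [build_corpus()] result.
#' @param dim Embedding dimension (default 30).
#' @param window Context window half-width (default 5).
#' @param epochs Training passes over the corpus (default 20).
#' @param seed Integer seed.
#' @param min_count Drop words seen fewer times than this (default 1).
#' @param negative Negative samples per centre word (default 5).
#' @param alpha,alpha_min Initial and final learning rate (linear decay).
#' @return An `embedding_model` with the word-vector matrix, output vectors,
#'   per-document vectors and the training configuration.
#' @export
train_embedding <- function(corpus, dim = 30, window = 5, epochs = 20,
                            seed = 1, min_count = 1, negative = 5,
                            alpha = 0.05, alpha_min = 1e-4) {
  if (length(corpus) == 0L) stop("empty corpus", call. = FALSE)
  word_len <- nchar(corpus[[1]][1])
  counts <- table(unlist(corpus, use.names = FALSE))
  kept <- counts[counts >= min_count]
  if (length(kept) == 0L) {
    warning("no word reaches min_count = ", min_count, "; keeping all words")
    kept <- counts
  }
  counts <- kept
  vocab <- stats::setNames(seq_along(counts), names(counts))
  docs <- lapply(corpus, function(ws) {
    ix <- vocab[ws]
    ix[is.na(ix)] <- 0L
    as.integer(ix) - 1L  # 0-based; -1 marks out-of-vocabulary
  })
  fit <- .pvdm_train(docs, as.numeric(counts), as.integer(dim),
                     as.integer(window), as.integer(epochs),
                     as.integer(negative), alpha, alpha_min, as.double(seed))
  rownames(fit$word) <- names(vocab)
  # Representation scale: emitted vectors are rescaled to unit RMS so the
  # downstream encoder sees O(1) inputs; model internals stay in the raw
  # scale used during training/inference.
  rms <- sqrt(mean(fit$word^2))
  structure(list(vocab = vocab, counts = as.numeric(counts),
                 scale = if (rms > 0) 1 / rms else 1,
                 word_vec = fit$word, out_vec = fit$out, doc_vec = fit$doc,
                 dim = as.integer(dim), window = as.integer(window),
                 word_len = as.integer(word_len), epochs = as.integer(epochs),
                 negative = as.integer(negative), alpha = alpha,
                 alpha_min = alpha_min, seed = seed),
            class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("<embedding_model> %d-mers, vocab %d, dim %d, window %d, seed %s\n",
              x$word_len, length(x$vocab), x$dim, x$window, format(x$seed)))
  invisible(x)
}

#' Infer a paragraph vector for a new sequence
#'
#' Word and output vectors stay frozen; only the new paragraph vector is
#' optimized. Reproducible for a fixed seed.
#'
#' @param model An [train_embedding()] model.
#' @param seq Nucleotide string (length >= `model$word_len`).
#' @param epochs Inference passes (default 20).
#' @param seed Seed for paragraph-vector initialization/negative draws.
#' @return Numeric vector of length `model$dim`.
#' @export
infer_vector <- function(model, seq, epochs = 20, seed = 1) {
  stopifnot(inherits(model, "embedding_model"))
  words <- build_corpus(seq, word_len = model$word_len)[[1]]
  ix <- model$vocab[words]
  ix[is.na(ix)] <- 0L
  .pvdm_infer(as.integer(ix) - 1L, model$word_vec, model$out_vec,
              model$counts, model$window, as.integer(epochs),
              model$negative, model$alpha, model$alpha_min, as.double(seed))
}

#' Encode one sequence under the embedding view
#'
#' In the default `"word"` mode, row `t` (for `t` in `1..L - word_len + 1`)
#' is the trained vector of the word starting at `t`; out-of-vocabulary words
#' give zero rows; the remaining rows are zero padding. In `"doc"` mode the
#' single inferred paragraph vector is tiled over the valid rows.
#'
#' @param seq Nucleotide string of length `L`.
#' @param model An [train_embedding()] model.
#' @param mode `"word"` (default) or `"doc"`.
#' @return A `view_features` object with an `L x dim` matrix and
#'   `valid_len = L - word_len + 1`.
#' @export
circrna2vec_encode <- function(seq, model, mode = c("word", "doc")) {
  stopifnot(inherits(model, "embedding_model"))
  mode <- match.arg(mode)
  L <- nchar(seq)
  if (L < model$word_len) {
    stop("sequence shorter than the model word length", call. = FALSE)
  }
  n <- L - model$word_len + 1L
  M <- matrix(0, L, model$dim)
  if (mode == "word") {
    words <- substring(seq, seq_len(n), seq_len(n) + model$word_len - 1L)
    ix <- model$vocab[words]
    hit <- which(!is.na(ix))
    if (length(hit)) {
      M[hit, ] <- model$word_vec[ix[hit], , drop = FALSE] * model$scale
    }
  } else {
    v <- infer_vector(model, seq, seed = model$seed) * model$scale
    M[seq_len(n), ] <- matrix(v, n, model$dim, byrow = TRUE)
  }
  view_features("CIRCRNA2VEC", M, valid_len = n)
}
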