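# Dataset-level view encoding. Encoded views for a whole dataset are held as
# stacked matrices ((N*L) x D, sample-major rows) so training batches are
# plain row slices; encoding is split-independent and computed once per
# dataset, while the label-dependent PSTNPss channel is fitted per training
# split and appended at fine-tuning time.

#' Encode every record under the three views
#'
#' @param records Tibble of sequence records sharing one length `L`.
#' @param embedding A trained [train_embedding()] model for the embedding
#'   view.
#' @param kmax Largest KNFP tuple size.
#' @return A `view_stacks` object: list with stacked matrices `$knfp`,
#'   `$c2v`, `$eiip`, plus `ids`, `N`, `L` and per-view channel widths.
#' @details The stacks carry fixed, data-independent per-view rescalings so
#'   every channel has O(1) dynamic range for the conv encoders: KNFP block
#'   `k` is multiplied by `4^k` (the inverse of the expected background
#'   k-tuple frequency), the EIIP channel by the reciprocal spread of the
#'   four EIIP constants, and embedding vectors are emitted at unit RMS by
#'   [circrna2vec_encode()]. Zero padding and zero (ambiguous-base) entries
#'   stay exactly zero. The raw, unscaled per-sequence encodings remain
#'   available from [knfp_encode()] and [eiip_encode()].
#' @export
encode_views <- function(records, embedding, kmax = 3) {
  assert_records(records)
  N <- nrow(records)
  L <- nchar(records$seq[1])
  if (any(nchar(records$seq) != L)) {
    stop("all sequences must share one length L", call. = FALSE)
  }
  d_knfp <- sum(4^seq_len(kmax))
  knfp <- matrix(0, N * L, d_knfp)
  c2v <- matrix(0, N * L, embedding$dim)
  eiip <- matrix(0, N * L, 1)
  knfp_scale <- rep(4^seq_len(kmax), times = 4^seq_len(kmax))
  eiip_scale <- 1 / sqrt(mean((eiip_values() - mean(eiip_values()))^2))
  for (i in seq_len(N)) {
    rows <- ((i - 1L) * L + 1L):(i * L)
    knfp[rows, ] <- knfp_encode(records$seq[i], kmax)$matrix *
      rep(knfp_scale, each = L)
    c2v[rows, ] <- circrna2vec_encode(records$seq[i], embedding)$matrix
    eiip[rows, ] <- eiip_encode(records$seq[i])$matrix * eiip_scale
  }
  structure(list(knfp = knfp, c2v = c2v, eiip = eiip, ids = records$id,
                 N = N, L = L,
                 dims = c(knfp = d_knfp, c2v = embedding$dim, eiip = 1L)),
            class = "view_stacks")
}

#' @export
print.view_stacks <- function(x, ...) {
  cat(sprintf("<view_stacks> %d records x L=%d; channels: knfp %d, c2v %d, eiip %d\n",
              x$N, x$L, x$dims["knfp"], x$dims["c2v"], x$dims["eiip"]))
  invisible(x)
}

# Rows of the stacked matrices for a set of sample indices.
stack_index_rows <- function(idx, L) {
  as.vector(vapply(idx, function(i) ((i - 1L) * L + 1L):(i * L),
                   integer(L)))
}

#' Fuse the per-view feature matrices of one sequence
#'
#' Channel-axis concatenation in fixed order (KNFP, embedding, EIIP); the
#' position axis is preserved. All views must be padded to the same `L`.
#'
#' @param views List of `view_features` for one sequence, in any order; views
#'   are arranged as KNFP, CIRCRNA2VEC, EIIP (missing views are skipped).
#' @return A `view_features` object with the concatenated matrix.
#' @export
#' @examples
#' # 84 + 30 + 1 channels fuse to 115
fuse_views <- function(views) {
  stopifnot(all(vapply(views, inherits, logical(1), "view_features")))
  order_tags <- c("KNFP", "CIRCRNA2VEC", "EIIP")
  tags <- vapply(views, `[[`, character(1), "view")
  views <- views[order(match(tags, order_tags))]
  Ls <- vapply(views, function(v) nrow(v$matrix), integer(1))
  if (length(unique(Ls)) != 1L) {
    stop("views must be padded to identical L before fusion", call. = FALSE)
  }
  view_features("FUSED", do.call(cbind, lapply(views, `[[`, "matrix")),
                valid_len = max(vapply(views, `[[`, integer(1), "valid_len")))
}

# Fused stacked matrix for a subset of samples, with optional PSTNPss channel
# appended after the EIIP block.
fused_stack <- function(stacks, idx, pstnpss_col = NULL) {
  rows <- stack_index_rows(idx, stacks$L)
  out <- cbind(stacks$knfp[rows, , drop = FALSE],
               stacks$c2v[rows, , drop = FALSE],
               stacks$eiip[rows, , drop = FALSE])
  if (!is.null(pstnpss_col)) out <- cbind(out, pstnpss_col)
  out
}
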