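# K-tuple nucleotide frequency pattern (KNFP) view.
#
# For each k in 1..kmax, position t holds a 4^k-wide row that is zero except in
# the column of the k-tuple starting at t, which holds that tuple's frequency
# in the sequence, count(tuple) / (L - k + 1). Blocks for k = 1, 2, 3 are
# concatenated column-wise (4 + 16 + 64 = 84 channels) and rows missing for
# larger k are zero-filled at the end. Tuples containing non-ACGT characters
# contribute an all-zero row for that k.

base_codes <- function(seq) {
  v <- strsplit(seq, "")[[1]]
  code <- match(v, c("A", "C", "G", "T")) - 1L  # NA for N etc.
  code
}

kmer_codes <- function(code, k) {
  L <- length(code)
  n <- L - k + 1L
  out <- integer(n)
  ok <- rep(TRUE, n)
  for (j in 0:(k - 1L)) {
    cj <- code[(1L + j):(n + j)]
    ok <- ok & !is.na(cj)
    out <- out * 4L + ifelse(is.na(cj), 0L, cj)
  }
  out[!ok] <- NA_integer_
  out
}

kmer_names <- function(k) {
  bases <- c("A", "C", "G", "T")
  g <- do.call(expand.grid, c(rep(list(bases), k), stringsAsFactors = FALSE))
  # first position is the most significant digit
  apply(g[, rev(seq_len(k)), drop = FALSE], 1L, paste0, collapse = "")
}

#' One unpadded KNFP block
#'
#' @param seq Nucleotide string (DNA alphabet).
#' @param k Tuple size.
#' @return A `(L - k + 1) x 4^k` matrix; column names are the k-tuples.
#' @export
knfp_block <- function(seq, k) {
  code <- base_codes(seq)
  L <- length(code)
  if (L < k) stop("sequence shorter than k", call. = FALSE)
  codes <- kmer_codes(code, k)
  n <- L - k + 1L
  counts <- tabulate(codes + 1L, nbins = 4L^k)
  freq <- counts / n
  M <- matrix(0, n, 4L^k, dimnames = list(NULL, kmer_names(k)))
  valid <- which(!is.na(codes))
  M[cbind(valid, codes[valid] + 1L)] <- freq[codes[valid] + 1L]
  M
}

#' Encode one sequence under the KNFP view
#'
#' @param seq Nucleotide string of length `L >= kmax`.
#' @param kmax Largest tuple size (default 3, giving 84 channels).
#' @return A `view_features` object: list with `view = "KNFP"`, an `L x 84`
#'   `matrix`, and `valid_len = L`.
#' @export
#' @examples
#' f <- knfp_encode(strrep("ACGT", 26), kmax = 3)
#' dim(f$matrix)
knfp_encode <- function(seq, kmax = 3) {
  L <- nchar(seq)
  if (L < kmax) stop("sequence length must be >= kmax", call. = FALSE)
  blocks <- lapply(seq_len(kmax), function(k) {
    B <- knfp_block(seq, k)
    rbind(B, matrix(0, L - nrow(B), ncol(B)))  # zero-fill at the end
  })
  view_features("KNFP", do.call(cbind, blocks), valid_len = L)
}

view_features <- function(view, matrix, valid_len) {
  structure(list(view = view, matrix = matrix, valid_len = as.integer(valid_len)),
            class = "view_features")
}

#' @export
print.view_features <- function(x, ...) {
  cat(sprintf("<view_features %s> %d x %d (valid rows: %d)\n",
              x$view, nrow(x$matrix), ncol(x$matrix), x$valid_len))
  invisible(x)
}
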