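# Electron-ion interaction pseudopotential (EIIP) view, optionally augmented
# with a position-specific trinucleotide propensity (PSTNPss) channel.

#' EIIP nucleotide constants
#'
#' The free-electron energy values used by the resonance recognition model:
#' G = 0.0806, C = 0.1340, T = 0.1335, A = 0.1260. Ambiguous bases map to 0.
#'
#' @return Named numeric vector over A, C, G, T.
#' @export
eiip_values <- function() {
  c(A = 0.1260, C = 0.1340, G = 0.0806, T = 0.1335)
}

#' Encode one sequence under the EIIP view
#'
#' @param seq Nucleotide string (DNA alphabet; apply U-to-T normalization at
#'   ingest, see [read_fasta()]).
#' @param pstnpss Optional [pstnpss_fit()] table; when supplied, its
#'   per-position propensity is appended as a second channel.
#' @return A `view_features` object with an `L x 1` (or `L x 2`) matrix and
#'   `valid_len = L`.
#' @export
#' @examples
#' eiip_encode("GCTA")$matrix[, 1]
eiip_encode <- function(seq, pstnpss = NULL) {
  v <- strsplit(seq, "")[[1]]
  vals <- unname(eiip_values()[v])
  vals[is.na(vals)] <- 0
  M <- matrix(vals, ncol = 1, dimnames = list(NULL, "EIIP"))
  if (!is.null(pstnpss)) {
    M <- cbind(M, PSTNPSS = pstnpss_encode(seq, pstnpss))
  }
  view_features("EIIP", M, valid_len = length(v))
}

#' Fit the position-specific trinucleotide propensity table
#'
#' For trinucleotide tau and start position j, the table entry is the
#' frequency of tau at j among positive-class sequences minus its frequency
#' among negative-class sequences; entries lie in `[-1, 1]`. The table is
#' class-conditional, so it must be fitted only on labeled *training*
#' sequences (fitting on test or pretraining data would leak labels).
#'
#' @param pos,neg Tibbles of sequence records of a common length `L`.
#' @return A `pstnpss_table`: a `64 x (L - 2)` matrix (rows named by
#'   trinucleotide) with attribute `L`.
#' @export
pstnpss_fit <- function(pos, neg) {
  assert_records(pos, "pos"); assert_records(neg, "neg")
  if (nrow(pos) == 0L || nrow(neg) == 0L) {
    stop("both classes must be non-empty to fit PSTNPss", call. = FALSE)
  }
  L <- nchar(pos$seq[1])
  if (any(nchar(c(pos$seq, neg$seq)) != L)) {
    stop("all sequences must share one length L", call. = FALSE)
  }
  count_class <- function(seqs) {
    counts <- matrix(0, 64, L - 2L)
    for (s in seqs) {
      codes <- kmer_codes(base_codes(s), 3L)
      ok <- which(!is.na(codes))
      idx <- cbind(codes[ok] + 1L, ok)
      counts[idx] <- counts[idx] + 1
    }
    counts / length(seqs)
  }
  tab <- count_class(pos$seq) - count_class(neg$seq)
  rownames(tab) <- kmer_names(3L)
  structure(tab, L = L, class = c("pstnpss_table", "matrix", "array"))
}

#' Per-position PSTNPss channel for one sequence
#'
#' Row `j` holds `table[seq[j..j+2], j]`; the last two rows (no complete
#' trinucleotide) and rows whose trinucleotide contains a non-ACGT base are 0.
#'
#' @param seq Nucleotide string of the length the table was fitted at.
#' @param table A [pstnpss_fit()] result.
#' @return Numeric vector of length `L`.
#' @export
pstnpss_encode <- function(seq, table) {
  stopifnot(inherits(table, "pstnpss_table"))
  L <- attr(table, "L")
  if (nchar(seq) != L) {
    stop("sequence length does not match the fitted table", call. = FALSE)
  }
  codes <- kmer_codes(base_codes(seq), 3L)
  out <- numeric(L)
  ok <- which(!is.na(codes))
  out[ok] <- table[cbind(codes[ok] + 1L, ok)]
  out
}
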