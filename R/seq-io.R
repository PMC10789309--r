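#' Read fixed-length sequence fragments from a FASTA file
#'
#' Sequences are uppercased and, by default, `U` is mapped to `T` so a single
#' DNA-alphabet lookup table serves all encoders. Characters outside
#' `A C G T N` are rejected; `N` is retained and encodes to zeros in every
#' view. All records in a dataset must share one length `L`.
#'
#' @param path FASTA file path.
#' @param label Optional label applied to every record (0 or 1). If `NULL`,
#'   a `label=0|1` token in the FASTA header is honoured when present.
#' @param L Expected fragment length; `NULL` accepts the (single) length found
#'   in the file.
#' @param u_to_t Map U to T at ingest (default `TRUE`).
#' @return A tibble with columns `id`, `seq` and `label` (integer or `NA`).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", strrep("ACGT", 25) , ">b", strrep("TGCA", 25)), fa)
#' read_fasta(fa, label = 1, L = 100)
read_fasta <- function(path, label = NULL, L = NULL, u_to_t = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    return(tibble::tibble(id = character(), seq = character(), label = integer()))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop(sprintf("malformed FASTA in '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  if (length(set) == 0L) {
    return(tibble::tibble(id = character(), seq = character(), label = integer()))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  seqs <- toupper(as.character(set))
  if (u_to_t) seqs <- gsub("U", "T", seqs, fixed = TRUE)

  bad <- grepl("[^ACGTUN]", seqs)
  if (any(bad)) {
    stop("records with characters outside {A,C,G,T,U,N}: ",
         paste(utils::head(ids[bad], 5L), collapse = ", "), call. = FALSE)
  }

  lens <- nchar(seqs)
  L <- L %||% lens[1L]
  if (any(lens != L)) {
    off <- ids[lens != L]
    stop(sprintf("length mismatch (expected L=%d): %s", L,
                 paste(utils::head(off, 5L), collapse = ", ")), call. = FALSE)
  }

  if (is.null(label)) {
    tok <- regmatches(headers, regexpr("label=[01]", headers))
    labels <- rep(NA_integer_, length(headers))
    has <- grepl("label=[01]", headers)
    labels[has] <- as.integer(sub("label=", "", tok))
  } else {
    stopifnot(label %in% c(0L, 1L))
    labels <- rep(as.integer(label), length(seqs))
  }
  tibble::tibble(id = ids, seq = unname(seqs), label = labels)
}

#' Read a paired positive/negative FASTA dataset
#'
#' The distribution format of CLIP-derived binding-site benchmarks: one FASTA
#' of bound fragments, one of unbound fragments.
#'
#' @inheritParams read_fasta
#' @param pos,neg Paths to the positive (label 1) and negative (label 0) FASTA.
#' @return A tibble with columns `id`, `seq`, `label`.
#' @export
read_fasta_pair <- function(pos, neg, L = NULL, u_to_t = TRUE) {
  p <- read_fasta(pos, label = 1L, L = L, u_to_t = u_to_t)
  n <- read_fasta(neg, label = 0L, L = L %||% (if (nrow(p)) nchar(p$seq[1]) else NULL),
                  u_to_t = u_to_t)
  dplyr::bind_rows(p, n)
}

#' Write sequence records to FASTA
#'
#' @param records Tibble with `id`, `seq` and optionally `label`.
#' @param path Output path.
#' @param with_label Append a `label=` token to headers when labels exist.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, with_label = FALSE) {
  assert_records(records)
  ids <- records$id
  if (with_label && "label" %in% names(records) && !all(is.na(records$label))) {
    ids <- paste0(ids, " label=", records$label)
  }
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Split records into train and test at a given ratio
#'
#' Records are shuffled with a seeded pseudo-random generator and partitioned;
#' `|train| = round(N * train/(train+test))` with the remainder going to test.
#' Identical inputs and seed always reproduce the identical split. By default
#' the shuffle ignores labels; `stratify = TRUE` splits within each class at
#' the same ratio (useful at tiny label budgets).
#'
#' @param records Tibble of sequence records.
#' @param ratio Length-2 positive integer vector `c(train_parts, test_parts)`,
#'   e.g. `c(1, 9)`.
#' @param seed Integer seed for the shuffle.
#' @param stratify Split within each label class (default `FALSE`).
#' @return A `dataset_split` list with tibbles `$train`, `$test` plus `$ratio`
#'   and `$seed`.
#' @export
#' @examples
#' d <- generate_dataset(fixture_config(n = 100, seed = 3))
#' s <- split_dataset(d, ratio = c(1, 9), seed = 7)
#' nrow(s$train); nrow(s$test)
split_dataset <- function(records, ratio = c(1, 9), seed = 1, stratify = FALSE) {
  assert_records(records)
  N <- nrow(records)
  if (N < 2L) stop("need at least 2 records to split", call. = FALSE)
  ratio <- as.integer(ratio)
  if (length(ratio) != 2L || any(ratio < 1L)) {
    stop("ratio must be two positive integers, e.g. c(1, 9)", call. = FALSE)
  }

  take_train <- function(n) round(n * ratio[1] / sum(ratio))

  local_seed(seed, {
    if (stratify && "label" %in% names(records) && !all(is.na(records$label))) {
      parts <- split(seq_len(N), records$label)
      tr_idx <- unlist(lapply(parts, function(ix) {
        ix <- ix[sample.int(length(ix))]
        ix[seq_len(take_train(length(ix)))]
      }), use.names = FALSE)
      perm <- sample.int(N)  # order within the final tibbles is still shuffled
      tr <- perm[perm %in% tr_idx]
      te <- perm[!perm %in% tr_idx]
    } else {
      perm <- sample.int(N)
      n_tr <- take_train(N)
      tr <- perm[seq_len(n_tr)]
      te <- perm[setdiff(seq_len(N), seq_len(n_tr))]
    }
    if (length(tr) == 0L || length(te) == 0L) {
      stop("degenerate ratio: produced an empty train or test set", call. = FALSE)
    }
    structure(list(train = records[tr, ], test = records[te, ],
                   ratio = ratio, seed = seed),
              class = "dataset_split")
  })
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %d train / %d test (ratio %d:%d, seed %s)\n",
              nrow(x$train), nrow(x$test), x$ratio[1], x$ratio[2],
              format(x$seed)))
  invisible(x)
}
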