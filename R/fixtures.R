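#' Describe a planted binding-site motif
#'
#' A motif is given as an IUPAC degenerate consensus (e.g. `"TGCATGRY"`).
#' When planted into a positive sequence, each degenerate position is resolved
#' uniformly among its allowed bases and every emitted base is then
#' independently mutated (replaced by one of the three other bases) with
#' probability `mutation_rate`.
#'
#' @param consensus IUPAC string over `A C G T R Y S W K M B D H V N`.
#' @param mutation_rate Per-base probability of deviation from the resolved
#'   consensus, in `[0, 0.5]`.
#' @param placement Integer vector of length 2: the range of allowed 1-based
#'   start offsets within the fragment, or `NULL` for anywhere it fits.
#' @return A `motif_spec` list.
#' @export
#' @examples
#' motif_spec("TGCATG", mutation_rate = 0.05)
motif_spec <- function(consensus, mutation_rate = 0.1, placement = NULL) {
  consensus <- toupper(consensus)
  bad <- setdiff(strsplit(consensus, "")[[1]], names(iupac_map()))
  if (length(bad) > 0) {
    stop("consensus contains non-IUPAC characters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (mutation_rate < 0 || mutation_rate > 0.5) {
    stop("mutation_rate must lie in [0, 0.5]", call. = FALSE)
  }
  structure(list(consensus = consensus, mutation_rate = mutation_rate,
                 placement = placement),
            class = "motif_spec")
}

iupac_map <- function() {
  list(A = "A", C = "C", G = "G", T = "T",
       R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
       K = c("G", "T"), M = c("A", "C"),
       B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
       V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
}

#' Configuration for the synthetic binding-site dataset generator
#'
#' The generator emulates CLIP-derived circRNA-RBP datasets: fixed-length
#' nucleotide fragments where positives carry one planted (degenerate, mutated)
#' motif occurrence at a random offset over i.i.d. background, and negatives
#' are pure background with the same base composition. Classes are exactly
#' balanced.
#'
#' @param n Total number of labeled fragments (must be even; `n/2` per class).
#' @param L Fragment length in nucleotides.
#' @param motifs A single [motif_spec()] or list of them; each positive gets
#'   one occurrence of one motif sampled uniformly from the list.
#' @param gc Background GC fraction in `(0, 1)`.
#' @param seed Integer seed; the same config always regenerates the same data.
#' @param background `"iid"` (independent bases) or `"markov1"` (first-order
#'   chain with persistence `markov_persist` toward repeating the previous
#'   base).
#' @param markov_persist Extra probability mass on repeating the previous base
#'   when `background = "markov1"`.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n = 2000, L = 101,
                           motifs = motif_spec("TGCATGRY", mutation_rate = 0.1),
                           gc = 0.5, seed = 1,
                           background = c("iid", "markov1"),
                           markov_persist = 0.25) {
  background <- match.arg(background)
  if (inherits(motifs, "motif_spec")) motifs <- list(motifs)
  stopifnot(n >= 2, n %% 2 == 0, L >= 1, gc > 0, gc < 1, length(motifs) >= 1)
  for (m in motifs) {
    if (nchar(m$consensus) >= L) {
      stop("motif consensus must be shorter than the fragment length L",
           call. = FALSE)
    }
  }
  structure(list(n = n, L = L, motifs = motifs, gc = gc, seed = seed,
                 background = background, markov_persist = markov_persist),
            class = "fixture_config")
}

base_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

sample_background <- function(n_seq, L, cfg) {
  p <- base_probs(cfg$gc)
  bases <- names(p)
  if (cfg$background == "iid") {
    mat <- matrix(sample(bases, n_seq * L, replace = TRUE, prob = p),
                  nrow = n_seq)
  } else {
    mat <- matrix("", n_seq, L)
    mat[, 1] <- sample(bases, n_seq, replace = TRUE, prob = p)
    for (t in 2:L) {
      fresh <- sample(bases, n_seq, replace = TRUE, prob = p)
      keep <- stats::runif(n_seq) < cfg$markov_persist
      mat[, t] <- ifelse(keep, mat[, t - 1], fresh)
    }
  }
  apply(mat, 1L, paste0, collapse = "")
}

instantiate_motif <- function(ms) {
  map <- iupac_map()
  letters <- strsplit(ms$consensus, "")[[1]]
  inst <- vapply(letters, function(ch) {
    opts <- map[[ch]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1))
  if (ms$mutation_rate > 0) {
    hit <- stats::runif(length(inst)) < ms$mutation_rate
    if (any(hit)) {
      inst[hit] <- vapply(inst[hit], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, character(1))
    }
  }
  paste0(inst, collapse = "")
}

#' Generate a labeled synthetic binding-site dataset
#'
#' Produces `cfg$n / 2` positive fragments (each containing one planted motif
#' occurrence at a random offset) and the same number of negative background
#' fragments. Fully seeded: the same `cfg` yields byte-identical output.
#'
#' @param cfg A [fixture_config()].
#' @return A tibble with columns `id`, `seq`, `label` (1 = site, 0 =
#'   background) and attribute `manifest` recording the generating parameters.
#' @export
#' @examples
#' d <- generate_dataset(fixture_config(n = 20, seed = 3))
#' table(d$label)
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "fixture_config"))
  local_seed(cfg$seed, {
    half <- cfg$n %/% 2L
    pos <- sample_background(half, cfg$L, cfg)
    neg <- sample_background(half, cfg$L, cfg)
    for (i in seq_len(half)) {
      ms <- cfg$motifs[[sample.int(length(cfg$motifs), 1L)]]
      inst <- instantiate_motif(ms)
      w <- nchar(inst)
      rng <- ms$placement %||% c(1L, cfg$L - w + 1L)
      rng[2] <- min(rng[2], cfg$L - w + 1L)
      at <- sample(seq.int(rng[1], rng[2]), 1L)
      substr(pos[i], at, at + w - 1L) <- inst
    }
    out <- tibble::tibble(
      id = c(sprintf("pos_%04d", seq_len(half)), sprintf("neg_%04d", seq_len(half))),
      seq = c(pos, neg),
      label = rep(c(1L, 0L), each = half)
    )
    attr(out, "manifest") <- unclass(cfg)[c("n", "L", "gc", "seed", "background")]
    out
  })
}

#' Generate an unlabeled background corpus for embedding training
#'
#' Stands in for a large splicing-sequence corpus: background-only fragments
#' (no planted motifs), optionally of varying lengths.
#'
#' @param cfg A [fixture_config()]; supplies background composition and `L`.
#' @param n_docs Number of corpus sequences.
#' @param lengths Optional integer vector of per-record lengths (recycled);
#'   defaults to `cfg$L` for every record.
#' @param seed Seed for the corpus stream; defaults to a stream derived from
#'   `cfg$seed` so corpus and labeled data are independent draws.
#' @return A tibble with columns `id`, `seq`.
#' @export
generate_corpus <- function(cfg, n_docs = 500, lengths = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "fixture_config"), n_docs >= 1)
  seed <- seed %||% child_seed(cfg$seed, 17L)
  lengths <- as.integer(rep_len(lengths %||% cfg$L, n_docs))
  local_seed(seed, {
    seqs <- vapply(lengths, function(L) sample_background(1L, L, cfg), character(1))
    tibble::tibble(id = sprintf("corpus_%05d", seq_len(n_docs)), seq = seqs)
  })
}
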