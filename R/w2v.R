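tokenize_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  substring(seq, seq_len(L - k + 1L), k:L)
}

#' Train a skip-gram k-mer embedding
#'
#' Treats each peptide as a sentence of overlapping k-mer tokens and trains
#' a skip-gram word-embedding model with negative sampling. Training is
#' single-threaded with a self-contained RNG, so a given seed always yields
#' identical vectors.
#'
#' @param corpus Character vector of sequences (or a `peptide_set`).
#' @param k k-mer token length (1..4).
#' @param dim Embedding dimension (default 128).
#' @param window Context window in tokens (default 40, i.e. effectively the
#'   whole peptide).
#' @param epochs Training epochs (default 100).
#' @param sg Architecture flag; only skip-gram (`1`) is implemented.
#' @param negative Negative samples per positive pair (default 5).
#' @param alpha,min_alpha Initial and final learning rate.
#' @param seed Integer seed (required).
#' @return A `w2v_model`: list with `vectors` (vocabulary-by-dim matrix,
#'   rownames = tokens), `k` and `dim`.
#' @export
train_w2v <- function(corpus, k, dim = 128L, window = 40L, epochs = 100L,
                      sg = 1L, negative = 5L, alpha = 0.025,
                      min_alpha = 1e-4, seed) {
  if (missing(seed)) stop("seed is required")
  if (sg != 1L) stop("only the skip-gram architecture (sg = 1) is implemented")
  k <- as.integer(k)
  stopifnot(k >= 1L, k <= 4L)
  seqs <- if (is.data.frame(corpus)) corpus$sequence else as.character(corpus)
  if (length(seqs) == 0L) stop("empty corpus")
  sentences <- lapply(seqs, tokenize_kmers, k = k)
  sentences <- sentences[lengths(sentences) > 0L]
  if (length(sentences) == 0L) stop("no sequence in the corpus is long enough for k = ", k)
  counts <- table(unlist(sentences))
  vocab <- sort(names(counts))
  counts <- as.numeric(counts[vocab])
  ids <- lapply(sentences, function(s) match(s, vocab) - 1L)
  vec <- .sgns_train(ids, length(vocab), as.integer(dim), as.integer(window),
                     as.integer(epochs), as.integer(negative), alpha,
                     min_alpha, counts, as.double(as.integer(seed)))
  rownames(vec) <- vocab
  colnames(vec) <- paste0("d", seq_len(ncol(vec)))
  structure(list(vectors = vec, k = k, dim = as.integer(dim)),
            class = "w2v_model")
}

#' Embed a peptide with a trained skip-gram model
#'
#' The sequence vector is the elementwise mean of the embedding vectors of
#' its overlapping k-mer tokens; out-of-vocabulary tokens are skipped, and
#' a fully out-of-vocabulary sequence yields the zero vector with a warning.
#'
#' @param seq Peptide sequence.
#' @param model A `w2v_model` from [train_w2v()].
#' @return Numeric vector of length `model$dim`.
#' @export
encode_w2v <- function(seq, model) {
  stopifnot(inherits(model, "w2v_model"))
  toks <- tokenize_kmers(check_seq(seq), model$k)
  hit <- toks[toks %in% rownames(model$vectors)]
  if (length(hit) == 0L) {
    warning("all k-mers out of vocabulary for sequence; zero vector returned")
    return(stats::setNames(numeric(model$dim), colnames(model$vectors)))
  }
  colMeans(model$vectors[hit, , drop = FALSE])
}
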