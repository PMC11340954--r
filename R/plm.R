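# Registry of protein-language-model embedding providers.
.plm_env <- new.env(parent = emptyenv())

#' Register a protein-language-model embedding provider
#'
#' A provider is a function `(sequences, dim) -> n x dim numeric matrix`
#' returning one mean-pooled vector per sequence. The built-in `"hash"`
#' provider is a synthetic deterministic stand-in (vectors seeded from a
#' sequence hash) so pipelines and tests run without any model download;
#' an adapter for a real transformer checkpoint can be registered under
#' any other name.
#'
#' @param name Provider name.
#' @param fn Embedding function `(sequences, dim)`.
#' @export
register_plm_provider <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  .plm_env[[name]] <- fn
  invisible(name)
}

seq_hash <- function(s) {
  codes <- utf8ToInt(s)
  h <- 7
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

hash_provider <- function(sequences, dim) {
  t(vapply(sequences, function(s) {
    rng <- local_rng(seq_hash(s))
    stats::rnorm(dim) / sqrt(dim)
  }, numeric(dim)))
}

#' Mean-pooled language-model embeddings for a set of peptides
#'
#' Looks up the named provider and returns one embedding vector per
#' sequence, optionally caching rows on disk keyed by a sequence hash so
#' repeated calls skip recomputation.
#'
#' @param seqs A `peptide_set` or character vector of sequences.
#' @param provider Provider name (default the deterministic `"hash"` stub).
#' @param dim Embedding dimension (default 32 for the stub).
#' @param cache_dir Optional directory for the on-disk embedding cache.
#' @return Numeric matrix, one row per sequence, `dim` columns.
#' @export
embed_plm <- function(seqs, provider = "hash", dim = 32L, cache_dir = NULL) {
  seqs <- if (is.data.frame(seqs)) seqs$sequence else as.character(seqs)
  fn <- .plm_env[[provider]]
  if (is.null(fn))
    stop("embedding provider '", provider, "' is not registered; ",
         "register one with register_plm_provider() or use the built-in ",
         "deterministic 'hash' stub (the classifier grid also runs without ",
         "any language-model column)")
  dim <- as.integer(dim)
  out <- matrix(NA_real_, nrow = length(seqs), ncol = dim)
  colnames(out) <- paste0("e", seq_len(dim))
  todo <- rep(TRUE, length(seqs))
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    keys <- vapply(seqs, function(s) sprintf("%s_%d_%d.tsv", provider, dim, seq_hash(s)), "")
    for (i in seq_along(seqs)) {
      f <- file.path(cache_dir, keys[i])
      if (file.exists(f)) {
        out[i, ] <- scan(f, quiet = TRUE)
        todo[i] <- FALSE
      }
    }
    if (any(!todo)) message("embedding cache hit for ", sum(!todo), " sequence(s)")
  }
  if (any(todo)) {
    uniq <- unique(seqs[todo])
    emb <- fn(uniq, dim)
    if (!is.matrix(emb) || nrow(emb) != length(uniq) || ncol(emb) != dim)
      stop("provider '", provider, "' returned a malformed embedding matrix")
    out[todo, ] <- emb[match(seqs[todo], uniq), , drop = FALSE]
    if (!is.null(cache_dir)) {
      for (i in which(todo)) {
        f <- file.path(cache_dir, keys[i])
        if (!file.exists(f))
          writeLines(formatC(out[i, ], digits = 17, format = "g"), f)
      }
    }
  }
  rownames(out) <- NULL
  out
}

.onLoad <- function(libname, pkgname) {
  register_plm_provider("hash", hash_provider)
}
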