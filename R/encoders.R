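#' Describe a feature encoding
#'
#' Builds an encoding specification naming one of the supported schemes and
#' its parameters. Per-residue schemes (BE, EAAC, BLOSUM62, ZSCALE) need an
#' `L_max`; embedding schemes (W2V_1..4, ESM2) take a trained model or
#' provider at encoding time.
#'
#' @param name Encoding name, one of `encoding_names()`.
#' @param ... Scheme parameters (`k`, `k_max`, `lam`, `w`, `window`,
#'   `L_max`, `dim`, ...).
#' @return An `encoding_spec` object.
#' @export
encoding_spec <- function(name, ...) {
  name <- toupper(name)
  if (!name %in% encoding_names())
    stop("unknown encoding '", name, "'; see encoding_names()")
  spec <- list(name = name, params = list(...))
  class(spec) <- "encoding_spec"
  spec
}

#' Names of the supported encodings
#'
#' @return Character vector of all encoding names understood by
#'   [encoding_spec()] and [encode_peptides()].
#' @export
encoding_names <- function() {
  c("AAC", "DPC", "TPC", "PAAC", "CKSAAP", "GAAC", "GDPC", "GTPC",
    "CTRIAD", "CTDC", "CTDT", "CTDD", "BE", "EAAC", "AAINDEX",
    "BLOSUM62", "ZSCALE", "ESM2", "W2V_1", "W2V_2", "W2V_3", "W2V_4", "NN")
}

kmer_names <- function(alphabet, k) {
  if (k == 1L) return(alphabet)
  grid <- expand.grid(rev(replicate(k, alphabet, simplify = FALSE)),
                      stringsAsFactors = FALSE)
  apply(grid[, rev(seq_len(k)), drop = FALSE], 1L, paste0, collapse = "")
}

split_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

check_seq <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) < 1L)
    stop("expected a single non-empty sequence string")
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", seq))
    stop("sequence contains non-standard residues: ", seq)
  seq
}

#' k-mer composition (AAC / DPC / TPC)
#'
#' Frequency of every length-`k` substring over the 20-letter alphabet:
#' component for k-mer q equals count(q) / (L - k + 1). k = 1, 2, 3 give
#' the 20-, 400- and 8000-dimensional amino-acid, dipeptide and tripeptide
#' compositions.
#'
#' @param seq Peptide sequence (single string).
#' @param k Substring length (1..3).
#' @return Named numeric vector of length `20^k`, summing to 1.
#' @export
encode_kmer <- function(seq, k = 1L) {
  check_seq(seq); k <- as.integer(k)
  stopifnot(k >= 1L, k <= 3L)
  L <- nchar(seq)
  if (L < k) stop("sequence shorter than k (L=", L, ", k=", k, ")")
  grams <- substring(seq, seq_len(L - k + 1L), k:L)
  tab <- table(factor(grams, levels = kmer_names(AA20, k)))
  out <- as.numeric(tab) / (L - k + 1L)
  names(out) <- kmer_names(AA20, k)
  out
}

#' Composition of k-spaced amino-acid pairs (CKSAAP)
#'
#' For every gap g = 0..k_max, the frequency of ordered residue pairs
#' (a, b) at positions (i, i + g + 1), normalized by the number of such
#' pairs (L - g - 1). The g = 0 block is exactly the dipeptide composition.
#' Gaps too large for the sequence yield an all-zero block with a warning.
#'
#' @param seq Peptide sequence.
#' @param k_max Largest gap (default 5, giving 2400 features).
#' @return Named numeric vector of length `400 * (k_max + 1)`.
#' @export
encode_cksaap <- function(seq, k_max = 5L) {
  check_seq(seq); k_max <- as.integer(k_max)
  stopifnot(k_max >= 0L)
  chars <- split_chars(seq)
  L <- length(chars)
  pair_names <- kmer_names(AA20, 2L)
  out <- numeric(0)
  for (g in 0:k_max) {
    n_pairs <- L - g - 1L
    if (n_pairs < 1L) {
      warning("gap ", g, " exceeds sequence length ", L, "; zero block emitted")
      block <- stats::setNames(numeric(400L), pair_names)
    } else {
      pairs <- paste0(chars[seq_len(n_pairs)], chars[seq_len(n_pairs) + g + 1L])
      block <- as.numeric(table(factor(pairs, levels = pair_names))) / n_pairs
      names(block) <- pair_names
    }
    names(block) <- paste0("g", g, ".", names(block))
    out <- c(out, block)
  }
  out
}

group_map <- function(groups) {
  map <- character(0)
  for (g in names(groups)) map[groups[[g]]] <- g
  map
}

#' Grouped composition (GAAC / GDPC / GTPC)
#'
#' The k-mer composition over the five-class physicochemical alphabet of
#' [gaac_groups()]: order 1, 2, 3 give 5, 25 and 125 features.
#'
#' @param seq Peptide sequence.
#' @param order Grouped k-mer length (1..3).
#' @return Named numeric vector summing to 1.
#' @export
encode_gaac <- function(seq, order = 1L) {
  check_seq(seq); order <- as.integer(order)
  stopifnot(order >= 1L, order <= 3L)
  chars <- split_chars(seq)
  L <- length(chars)
  if (L < order) stop("sequence shorter than order")
  map <- group_map(gaac_groups())
  gseq <- map[chars]
  lv <- kmer_names(names(gaac_groups()), order)
  grams <- vapply(seq_len(L - order + 1L),
                  function(i) paste0(gseq[i:(i + order - 1L)], collapse = ""), "")
  out <- as.numeric(table(factor(grams, levels = lv))) / (L - order + 1L)
  names(out) <- lv
  out
}

#' Conjoint triad composition
#'
#' Frequencies of consecutive residue triples under the seven-class
#' alphabet of [ctriad_groups()], normalized by the triad count (L - 2).
#'
#' @param seq Peptide sequence of length at least 3.
#' @return Named numeric vector of length 343, summing to 1.
#' @export
encode_ctriad <- function(seq) {
  check_seq(seq)
  chars <- split_chars(seq)
  L <- length(chars)
  if (L < 3L) stop("conjoint triad needs L >= 3")
  map <- group_map(ctriad_groups())
  gseq <- map[chars]
  lv <- kmer_names(names(ctriad_groups()), 3L)
  triads <- paste0(gseq[1:(L - 2L)], gseq[2:(L - 1L)], gseq[3:L])
  out <- as.numeric(table(factor(triads, levels = lv))) / (L - 2L)
  names(out) <- lv
  out
}

#' Composition/Transition/Distribution descriptors
#'
#' For each of the 13 three-group physicochemical properties of
#' [ctd_groups()]:
#' * `C` — the fraction of residues in each group (3 values per property,
#'   39 total; each property's triple sums to 1);
#' * `T` — the frequency of adjacent residue pairs whose groups differ,
#'   one value per unordered group pair, normalized by (L - 1) (39 total);
#' * `D` — for each group, the sequence positions (as percent of L) of its
#'   first occurrence and of the occurrences at 25, 50, 75 and 100 percent
#'   of its count, 0 when the group is absent (195 total).
#'
#' @param seq Peptide sequence.
#' @param part One of `"C"`, `"T"`, `"D"`.
#' @return Named numeric vector of length 39, 39 or 195.
#' @export
encode_ctd <- function(seq, part = c("C", "T", "D")) {
  part <- match.arg(part)
  check_seq(seq)
  chars <- split_chars(seq)
  L <- length(chars)
  if (part == "T" && L < 2L) stop("CTD transition needs L >= 2")
  props <- ctd_groups()
  out <- numeric(0)
  for (p in names(props)) {
    gs <- lapply(props[[p]], function(s) strsplit(s, "")[[1]])
    map <- character(0)
    for (gi in 1:3) map[gs[[gi]]] <- paste0("g", gi)
    gseq <- map[chars]
    if (part == "C") {
      v <- as.numeric(table(factor(gseq, levels = c("g1", "g2", "g3")))) / L
      names(v) <- paste0(p, ".", c("g1", "g2", "g3"))
    } else if (part == "T") {
      a <- gseq[-L]; b <- gseq[-1L]
      pair <- paste0(pmin(a, b), pmax(a, b))
      v <- as.numeric(table(factor(pair[a != b],
                                   levels = c("g1g2", "g1g3", "g2g3")))) / (L - 1L)
      names(v) <- paste0(p, ".", c("g1g2", "g1g3", "g2g3"))
    } else {
      v <- numeric(0)
      for (gi in c("g1", "g2", "g3")) {
        pos <- which(gseq == gi)
        N <- length(pos)
        pct <- if (N == 0L) rep(0, 5) else {
          targets <- c(1L, pmax(1L, ceiling(N * c(0.25, 0.5, 0.75))), N)
          100 * pos[targets] / L
        }
        names(pct) <- paste0(p, ".", gi, ".p", c(0, 25, 50, 75, 100))
        v <- c(v, pct)
      }
    }
    out <- c(out, v)
  }
  out
}

#' Pseudo-amino-acid composition (PAAC)
#'
#' Chou's formulation: the 20 residue frequencies augmented with `lam`
#' sequence-order correlation factors. Properties (hydrophobicity,
#' hydrophilicity, side-chain mass from [paac_properties()]) are
#' standardized over the 20 residues; the rank-d factor is the mean over
#' positions of the mean squared property difference between residues d
#' apart. Components are jointly normalized by `1 + w * sum(theta)`.
#'
#' @param seq Peptide sequence with `nchar(seq) > lam`.
#' @param lam Number of correlation ranks (default 5, giving 25 features).
#' @param w Weight of the sequence-order part (default 0.05).
#' @return Named numeric vector of length `20 + lam`.
#' @export
encode_paac <- function(seq, lam = 5L, w = 0.05) {
  check_seq(seq); lam <- as.integer(lam)
  stopifnot(lam >= 0L, w >= 0)
  chars <- split_chars(seq)
  L <- length(chars)
  if (L <= lam) stop("PAAC needs L > lam (L=", L, ", lam=", lam, ")")
  props <- paac_properties()
  zprops <- t(apply(props, 1L, function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))))
  freqs <- as.numeric(table(factor(chars, levels = AA20))) / L
  theta <- numeric(lam)
  if (lam > 0L) {
    for (d in seq_len(lam)) {
      i <- seq_len(L - d)
      corr <- colMeans((zprops[, chars[i + d], drop = FALSE] -
                          zprops[, chars[i], drop = FALSE])^2)
      theta[d] <- mean(corr)
    }
  }
  denom <- 1 + w * sum(theta)
  out <- c(freqs / denom, if (lam > 0L) w * theta / denom)
  names(out) <- c(AA20, if (lam > 0L) paste0("theta", seq_len(lam)))
  out
}

#' One-hot binary encoding (BE)
#'
#' Each residue becomes a 20-bit indicator block in alphabet order;
#' positions past the end of the sequence are zero padding.
#'
#' @param seq Peptide sequence with `nchar(seq) <= L_max`.
#' @param L_max Padded length.
#' @param truncate Truncate longer sequences instead of erroring.
#' @return Numeric vector of length `20 * L_max`.
#' @export
encode_binary <- function(seq, L_max, truncate = FALSE) {
  check_seq(seq)
  chars <- clip_to_lmax(seq, L_max, truncate)
  out <- matrix(0, nrow = 20L, ncol = L_max, dimnames = list(AA20, NULL))
  out[cbind(match(chars, AA20), seq_along(chars))] <- 1
  flatten_positional(out)
}

#' Sliding-window amino-acid composition (EAAC)
#'
#' A window of fixed length slides from the N- to the C-terminus; each
#' window contributes the 20 within-window residue frequencies
#' (count / window). Windows beyond the real sequence are zero-padded.
#'
#' @param seq Peptide sequence with `nchar(seq) >= window`.
#' @param window Window length (default 5).
#' @param L_max Padded length (default the sequence length).
#' @return Numeric vector of length `20 * (L_max - window + 1)`.
#' @export
encode_eaac <- function(seq, window = 5L, L_max = nchar(seq)) {
  check_seq(seq); window <- as.integer(window)
  chars <- split_chars(seq)
  L <- length(chars)
  if (L < window) stop("EAAC needs L >= window")
  if (L > L_max) stop("sequence longer than L_max")
  n_win <- L_max - window + 1L
  out <- matrix(0, nrow = 20L, ncol = n_win, dimnames = list(AA20, NULL))
  for (j in seq_len(L - window + 1L)) {
    win <- chars[j:(j + window - 1L)]
    out[, j] <- as.numeric(table(factor(win, levels = AA20))) / window
  }
  names_out <- as.vector(outer(AA20, seq_len(n_win),
                               function(a, p) paste0("w", p, ".", a)))
  v <- as.vector(out)
  names(v) <- names_out
  v
}

#' Mean AAindex physicochemical profile
#'
#' One component per AAindex property: the mean of that property's values
#' over the residues of the sequence. With the full bundled snapshot the
#' vector has 531 components.
#'
#' @param seq Peptide sequence.
#' @param table Index-by-residue matrix (default [aaindex_table()]).
#' @return Named numeric vector, one value per index.
#' @export
encode_aaindex <- function(seq, table = aaindex_table()) {
  check_seq(seq)
  chars <- split_chars(seq)
  if (!all(chars %in% colnames(table)))
    stop("residue absent from AAindex table: ",
         paste(setdiff(chars, colnames(table)), collapse = ", "))
  out <- rowMeans(table[, chars, drop = FALSE])
  names(out) <- rownames(table)
  out
}

#' Positional BLOSUM62 encoding
#'
#' Each residue contributes its 20-value BLOSUM62 substitution row; zero
#' padding past the end of the sequence.
#'
#' @inheritParams encode_binary
#' @return Numeric vector of length `20 * L_max`.
#' @export
encode_blosum62 <- function(seq, L_max, truncate = FALSE) {
  check_seq(seq)
  chars <- clip_to_lmax(seq, L_max, truncate)
  m <- blosum62_matrix()
  out <- matrix(0, nrow = 20L, ncol = L_max, dimnames = list(colnames(m), NULL))
  out[, seq_along(chars)] <- t(m[chars, , drop = FALSE])
  flatten_positional(out)
}

#' Positional z-scale encoding
#'
#' Each residue contributes its five z-scale descriptors; zero padding past
#' the end of the sequence.
#'
#' @inheritParams encode_binary
#' @return Numeric vector of length `5 * L_max`.
#' @export
encode_zscale <- function(seq, L_max, truncate = FALSE) {
  check_seq(seq)
  chars <- clip_to_lmax(seq, L_max, truncate)
  zt <- zscale_table()
  out <- matrix(0, nrow = 5L, ncol = L_max, dimnames = list(colnames(zt), NULL))
  out[, seq_along(chars)] <- t(zt[chars, , drop = FALSE])
  flatten_positional(out)
}

clip_to_lmax <- function(seq, L_max, truncate) {
  L_max <- as.integer(L_max)
  chars <- split_chars(seq)
  if (length(chars) > L_max) {
    if (!truncate) stop("sequence length ", length(chars), " exceeds L_max ", L_max)
    chars <- chars[seq_len(L_max)]
  }
  chars
}

flatten_positional <- function(m) {
  v <- as.vector(m)
  names(v) <- as.vector(outer(rownames(m), seq_len(ncol(m)),
                              function(a, p) paste0("pos", p, ".", a)))
  v
}

#' Dimension of an encoding
#'
#' @param spec An `encoding_spec`.
#' @param L_max Padded length for per-residue schemes (overrides the spec).
#' @return Integer feature count.
#' @export
encoding_dim <- function(spec, L_max = spec$params$L_max) {
  p <- spec$params
  switch(spec$name,
    AAC = 20L, DPC = 400L, TPC = 8000L,
    PAAC = 20L + as.integer(p$lam %||% 5L),
    CKSAAP = 400L * (as.integer(p$k_max %||% 5L) + 1L),
    GAAC = 5L, GDPC = 25L, GTPC = 125L,
    CTRIAD = 343L, CTDC = 39L, CTDT = 39L, CTDD = 195L,
    BE = 20L * need_lmax(L_max),
    EAAC = 20L * (need_lmax(L_max) - as.integer(p$window %||% 5L) + 1L),
    AAINDEX = nrow(p$table %||% aaindex_table()),
    BLOSUM62 = 20L * need_lmax(L_max),
    ZSCALE = 5L * need_lmax(L_max),
    ESM2 = as.integer(p$dim %||% 32L),
    NN = stop("NN is a learned embedding with no fixed vector form"),
    {
      if (grepl("^W2V_", spec$name)) as.integer(p$dim %||% 128L)
      else stop("no dimension rule for ", spec$name)
    })
}

need_lmax <- function(L_max) {
  if (is.null(L_max)) stop("this encoding needs L_max (padded length)")
  as.integer(L_max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Encode a set of peptides as a feature matrix
#'
#' Applies one encoding to every sequence, producing an n-by-p numeric
#' matrix with feature names. Per-residue schemes default `L_max` to the
#' longest sequence in `ds`; embedding schemes read the trained model or
#' provider from the spec parameters (`model` for W2V_k, `provider`/`dim`
#' for ESM2).
#'
#' @param ds A `peptide_set` or character vector of sequences.
#' @param spec An `encoding_spec` (or encoding name).
#' @return Numeric matrix with one row per peptide; attribute `encoding`
#'   carries the spec (with any defaulted `L_max` filled in).
#' @export
encode_peptides <- function(ds, spec) {
  if (is.character(spec)) spec <- encoding_spec(spec)
  seqs <- if (is.data.frame(ds)) ds$sequence else as.character(ds)
  if (length(seqs) == 0L) stop("no sequences to encode")
  p <- spec$params
  if (spec$name %in% c("BE", "EAAC", "BLOSUM62", "ZSCALE") && is.null(p$L_max))
    spec$params$L_max <- p$L_max <- max(nchar(seqs))
  enc_one <- switch(spec$name,
    AAC = function(s) encode_kmer(s, 1L),
    DPC = function(s) encode_kmer(s, 2L),
    TPC = function(s) encode_kmer(s, 3L),
    PAAC = function(s) encode_paac(s, p$lam %||% 5L, p$w %||% 0.05),
    CKSAAP = function(s) encode_cksaap(s, p$k_max %||% 5L),
    GAAC = function(s) encode_gaac(s, 1L),
    GDPC = function(s) encode_gaac(s, 2L),
    GTPC = function(s) encode_gaac(s, 3L),
    CTRIAD = encode_ctriad,
    CTDC = function(s) encode_ctd(s, "C"),
    CTDT = function(s) encode_ctd(s, "T"),
    CTDD = function(s) encode_ctd(s, "D"),
    BE = function(s) encode_binary(s, p$L_max, isTRUE(p$truncate)),
    EAAC = function(s) encode_eaac(s, p$window %||% 5L, p$L_max),
    AAINDEX = function(s) encode_aaindex(s, p$table %||% aaindex_table()),
    BLOSUM62 = function(s) encode_blosum62(s, p$L_max, isTRUE(p$truncate)),
    ZSCALE = function(s) encode_zscale(s, p$L_max, isTRUE(p$truncate)),
    ESM2 = NULL, NN = NULL,
    if (grepl("^W2V_", spec$name)) NULL else stop("unsupported encoding ", spec$name))
  if (spec$name == "ESM2") {
    m <- embed_plm(seqs, provider = p$provider %||% "hash",
                   dim = p$dim %||% 32L, cache_dir = p$cache_dir)
  } else if (grepl("^W2V_", spec$name)) {
    if (is.null(p$model))
      stop(spec$name, " needs a trained skip-gram model in params$model (see train_w2v)")
    m <- t(vapply(seqs, function(s) encode_w2v(s, p$model),
                  numeric(p$model$dim)))
    rownames(m) <- NULL
  } else if (spec$name == "NN") {
    stop("NN encoding is only consumed by the optional deep-model plugin")
  } else {
    m <- t(vapply(seqs, enc_one, numeric(encoding_dim(spec))))
    rownames(m) <- NULL
  }
  if (any(!is.finite(m)))
    stop("non-finite values produced by encoding ", spec$name)
  attr(m, "encoding") <- spec
  m
}
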