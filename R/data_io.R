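#' Construct a labeled peptide dataset
#'
#' The central data container: a data frame with one row per peptide and
#' columns `id`, `sequence`, `label` (0/1 or NA when unlabeled), `split`
#' (`"train"`/`"test"` or NA) and `fold` (0-based fold id for train rows,
#' NA otherwise).
#'
#' @param id Character vector of record identifiers.
#' @param sequence Character vector of upper-case amino-acid sequences.
#' @param label Optional 0/1 integer vector.
#' @param split Optional character vector (`"train"`/`"test"`).
#' @param fold Optional integer vector of fold ids for train rows.
#' @param nonstandard Policy for sequences containing residues outside the
#'   20-letter alphabet: `"error"` (default) or `"drop"`.
#' @return A `peptide_set` data frame.
#' @export
peptide_set <- function(id, sequence, label = NA_integer_, split = NA_character_,
                        fold = NA_integer_, nonstandard = c("error", "drop")) {
  nonstandard <- match.arg(nonstandard)
  sequence <- toupper(as.character(sequence))
  n <- length(sequence)
  if (n == 0L) stop("peptide_set: no sequences supplied")
  if (missing(id) || is.null(id)) id <- sprintf("pep%04d", seq_len(n))
  id <- as.character(id)
  stopifnot(length(id) == n)
  label <- rep_len(as.integer(label), n)
  if (!all(is.na(label) | label %in% c(0L, 1L)))
    stop("labels must be 0, 1 or NA")
  bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", sequence)
  if (any(bad)) {
    if (nonstandard == "error")
      stop("non-standard or empty sequence in record(s): ",
           paste(id[bad], collapse = ", "))
    id <- id[!bad]; sequence <- sequence[!bad]; label <- label[!bad]
    if (length(sequence) == 0L) stop("all records rejected by validation")
    n <- length(sequence)
  }
  ds <- data.frame(
    id = id, sequence = sequence, label = label,
    split = rep_len(as.character(split), n),
    fold = rep_len(as.integer(fold), n),
    stringsAsFactors = FALSE
  )
  class(ds) <- c("peptide_set", "data.frame")
  ds
}

#' @export
print.peptide_set <- function(x, ...) {
  cat(sprintf("peptide_set: %d peptides (%d positive, %d negative, %d unlabeled)\n",
              nrow(x), sum(x$label == 1L, na.rm = TRUE),
              sum(x$label == 0L, na.rm = TRUE), sum(is.na(x$label))))
  if (any(!is.na(x$split)))
    cat(sprintf("  split: %d train / %d test\n",
                sum(x$split == "train", na.rm = TRUE),
                sum(x$split == "test", na.rm = TRUE)))
  if (any(!is.na(x$fold)))
    cat(sprintf("  folds: %s\n", paste(sort(unique(stats::na.omit(x$fold))), collapse = " ")))
  invisible(x)
}

#' Read peptides from a FASTA file
#'
#' Headers of the form `>id|label=1` carry the binary label; other headers
#' yield unlabeled records. `|split=` and `|fold=` tokens written by
#' [write_fasta()] are also recognised, so a write/read round trip is exact.
#'
#' @param path FASTA file (wrapped or unwrapped lines).
#' @param nonstandard Validation policy, see [peptide_set()].
#' @return A `peptide_set`.
#' @export
read_fasta <- function(path, nonstandard = c("error", "drop")) {
  nonstandard <- match.arg(nonstandard)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  parts <- strsplit(headers, "|", fixed = TRUE)
  id <- vapply(parts, `[`, "", 1L)
  grab <- function(p, key) {
    hit <- grep(paste0("^", key, "="), p, value = TRUE)
    if (length(hit)) sub(paste0("^", key, "="), "", hit[1L]) else NA_character_
  }
  label <- vapply(parts, grab, "", key = "label")
  split <- vapply(parts, grab, "", key = "split")
  fold <- vapply(parts, grab, "", key = "fold")
  if (!all(is.na(label) | label %in% c("0", "1")))
    stop("FASTA labels must be 0 or 1")
  peptide_set(id = id, sequence = as.character(set),
              label = as.integer(label), split = split,
              fold = as.integer(fold), nonstandard = nonstandard)
}

#' Write a peptide dataset to FASTA
#'
#' Labels, split tags and fold ids present in the dataset are appended to
#' the header as `|label=`, `|split=`, `|fold=` tokens.
#'
#' @param ds A `peptide_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ds, path) {
  hdr <- ds$id
  hdr <- ifelse(is.na(ds$label), hdr, paste0(hdr, "|label=", ds$label))
  hdr <- ifelse(is.na(ds$split), hdr, paste0(hdr, "|split=", ds$split))
  hdr <- ifelse(is.na(ds$fold), hdr, paste0(hdr, "|fold=", ds$fold))
  writeLines(paste0(">", hdr, "\n", ds$sequence), path)
  invisible(path)
}

#' Read a peptide dataset from CSV
#'
#' Expects columns `sequence` and `label` (0/1); optional `id`, `split`,
#' `fold` columns are honoured. Duplicate sequences are kept with a warning.
#'
#' @param path CSV file with a header row.
#' @param nonstandard Validation policy, see [peptide_set()].
#' @return A `peptide_set`.
#' @export
read_csv_dataset <- function(path, nonstandard = c("error", "drop")) {
  nonstandard <- match.arg(nonstandard)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("sequence", "label") %in% names(df)))
    stop("CSV must have 'sequence' and 'label' columns")
  if (nrow(df) == 0L) stop("empty CSV dataset: ", path)
  lab <- trimws(df$label)
  bad <- is.na(lab) | lab == "" | !(lab %in% c("0", "1"))
  if (any(bad))
    stop("invalid label at row(s): ", paste(which(bad), collapse = ", "),
         " (labels must be 0 or 1)")
  if (anyDuplicated(df$sequence))
    warning("duplicate sequences present (kept): ",
            sum(duplicated(df$sequence)), " record(s)")
  peptide_set(
    id = if ("id" %in% names(df)) df$id else NULL,
    sequence = df$sequence, label = as.integer(lab),
    split = if ("split" %in% names(df)) df$split else NA_character_,
    fold = if ("fold" %in% names(df)) as.integer(df$fold) else NA_integer_,
    nonstandard = nonstandard
  )
}

#' Write a peptide dataset to CSV
#'
#' @param ds A `peptide_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_csv_dataset <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Stratified train/test split
#'
#' Splits each class separately: `floor(n_class * test_fraction)` records go
#' to the test set, the remainder to training (so a 313/2908 dataset at 0.2
#' yields a 62/581 test set). No resampling is applied: class counts are
#' preserved exactly.
#'
#' @param ds A labeled `peptide_set`.
#' @param test_fraction Fraction per class assigned to the test split.
#' @param seed Integer seed controlling the membership draw.
#' @return The dataset with its `split` column filled.
#' @export
stratified_split <- function(ds, test_fraction = 0.2, seed) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  if (missing(seed)) stop("seed is required")
  if (any(is.na(ds$label))) stop("stratified_split requires labels on all records")
  counts <- table(factor(ds$label, levels = c(0L, 1L)))
  if (any(counts < 2L)) stop("each class needs at least 2 members to split")
  split <- rep("train", nrow(ds))
  rng <- local_rng(seed)
  for (cl in c(0L, 1L)) {
    idx <- which(ds$label == cl)
    n_test <- floor(length(idx) * test_fraction)
    split[sample(idx, n_test)] <- "test"
  }
  ds$split <- split
  ds$fold <- NA_integer_
  ds
}

#' Assign stratified cross-validation folds to the training split
#'
#' Within each class, training records are shuffled and dealt round-robin
#' into `n_folds` folds, so per-fold class counts differ by at most one.
#'
#' @param ds A `peptide_set` with `split` assigned.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed.
#' @return The dataset with `fold` filled on train rows (0-based ids).
#' @export
assign_folds <- function(ds, n_folds = 5L, seed) {
  if (missing(seed)) stop("seed is required")
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("n_folds must be at least 2")
  tr <- which(ds$split == "train")
  if (length(tr) == 0L) stop("no training rows; run stratified_split first")
  if (any(is.na(ds$label[tr]))) stop("training rows must be labeled")
  for (cl in c(0L, 1L))
    if (sum(ds$label[tr] == cl) < n_folds)
      stop("class ", cl, " has fewer members than folds")
  fold <- rep(NA_integer_, nrow(ds))
  rng <- local_rng(seed)
  for (cl in c(0L, 1L)) {
    idx <- tr[ds$label[tr] == cl]
    idx <- sample(idx)
    fold[idx] <- rep_len(0:(n_folds - 1L), length(idx))
  }
  ds$fold <- fold
  ds
}

# Scoped RNG: seeds the session RNG and restores the previous state when the
# calling frame exits, so package functions never leak RNG state.
local_rng <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  withr::defer({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, envir = envir)
  set.seed(as.integer(seed))
  invisible(seed)
}
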