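new_trace <- function(method, steps, plateau_eps = 0.002) {
  df <- do.call(rbind, lapply(steps, function(s) {
    data.frame(method = method, X = s$X,
               members = paste(s$members, collapse = ";"),
               auc = s$auc, mcc = s$mcc, stringsAsFactors = FALSE)
  }))
  df <- df[order(df$X), , drop = FALSE]
  rownames(df) <- NULL
  best <- df$X[which.max(df$auc)]  # ties -> smallest X (first maximum)
  structure(df,
            member_sets = stats::setNames(lapply(steps[order(vapply(steps, `[[`, 0L, "X"))],
                                                 `[[`, "members"), df$X),
            awclr_steps = stats::setNames(lapply(steps[order(vapply(steps, `[[`, 0L, "X"))],
                                                 `[[`, "awclr"), df$X),
            best_X = best,
            plateau_X = detect_plateau(df$X, df$auc, plateau_eps),
            class = c("selection_trace", "data.frame"))
}

# Smallest X opening a run of >= min_len consecutive steps whose AUC stays
# within eps of the global maximum; NA when no such run exists.
detect_plateau <- function(X, auc, eps = 0.002, min_len = 3L) {
  ok <- auc >= max(auc) - eps
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= min_len)
  if (length(hit) == 0L) return(NA_integer_)
  X[starts[hit[1L]]]
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("%s selection trace over %d subset sizes; best X = %d (AUC %.3f)",
              x$method[1L], nrow(x), attr(x, "best_X"),
              max(x$auc)))
  if (!is.na(attr(x, "plateau_X")))
    cat(sprintf("; plateau from X = %d", attr(x, "plateau_X")))
  cat("\n")
  invisible(x)
}

#' Sequential addition by AUC rank (SAAUC)
#'
#' Ranks the single-feature models by cross-validated AUC (descending,
#' ties by model key) and, for X = 1..n, fits the meta-classifier on the
#' top-X probability columns, recording validation AUC and MCC from the
#' meta-level out-of-fold probabilities. Subsets are nested.
#'
#' @param models List of `single_feature_model`s.
#' @param pm Their `probability_matrix`.
#' @param meta_name Meta-classifier (default `"LR"`).
#' @param seed Integer seed.
#' @return A `selection_trace`.
#' @export
saauc <- function(models, pm, meta_name = "LR", seed = 42L) {
  ranking <- rank_models_by_auc(models)$model_key
  steps <- lapply(seq_along(ranking), function(X) {
    meta <- fit_meta(subset_pm(pm, ranking[seq_len(X)]), meta_name, seed)
    list(X = X, members = ranking[seq_len(X)],
         auc = meta$cv_metrics$AUC, mcc = meta$cv_metrics$MCC, awclr = NULL)
  })
  new_trace("SAAUC", steps)
}

#' Sequential addition by AWCLR rank (SAWC)
#'
#' Fits the LR meta-classifier once on all probability columns, ranks the
#' models by the absolute value of their weight coefficients (AWCLR,
#' descending; ties by model key) and, for X = 1..n, fits the
#' meta-classifier on the top-X columns. The ranking is computed once and
#' never updated, so subsets are nested.
#'
#' @inheritParams saauc
#' @return A `selection_trace`.
#' @export
sawc <- function(models, pm, seed = 42L) {
  full <- fit_meta(pm, "LR", seed)
  aw <- extract_awclr(full)
  ranking <- names(aw)[order(-aw, names(aw))]
  steps <- lapply(seq_along(ranking), function(X) {
    meta <- fit_meta(subset_pm(pm, ranking[seq_len(X)]), "LR", seed)
    list(X = X, members = ranking[seq_len(X)],
         auc = meta$cv_metrics$AUC, mcc = meta$cv_metrics$MCC, awclr = NULL)
  })
  new_trace("SAWC", steps)
}

#' Sequential deletion with iteratively updated AWCLR ranking (SDIWC)
#'
#' The backward-elimination loop: (1) fit the LR meta-classifier on the
#' remaining columns and compute every member's AWCLR; (2) sort by AWCLR;
#' (3) delete the member with the lowest AWCLR (ties: the
#' lexicographically last model key); (4) refit on the remainder;
#' (5) repeat until one member remains. One trace record is written per
#' subset size X = n..1, so consecutive member sets differ by exactly the
#' deleted model.
#'
#' @inheritParams saauc
#' @return A `selection_trace` (with the per-step AWCLR maps attached).
#' @export
sdiwc <- function(models, pm, seed = 42L) {
  remaining <- attr(pm, "model_keys")
  if (length(remaining) < 2L) stop("SDIWC needs at least 2 models")
  steps <- list()
  while (length(remaining) >= 1L) {
    meta <- fit_meta(subset_pm(pm, remaining), "LR", seed)
    aw <- if (length(remaining) > 1L) extract_awclr(meta) else
      stats::setNames(abs(meta$coefficients[-1L]), remaining)
    steps[[length(steps) + 1L]] <- list(
      X = length(remaining), members = remaining,
      auc = meta$cv_metrics$AUC, mcc = meta$cv_metrics$MCC, awclr = aw)
    if (length(remaining) == 1L) break
    worst <- names(aw)[aw == min(aw)]
    drop_key <- sort(worst)[length(worst)]  # lexicographically last on ties
    remaining <- setdiff(remaining, drop_key)
  }
  new_trace("SDIWC", steps)
}

#' Accuracy pre-filter against the majority-class baseline
#'
#' Computes the all-negative baseline accuracy N_neg / (N_neg + N_pos)
#' from the training labels (never hard-coded) and keeps the models whose
#' cross-validated accuracy reaches it.
#'
#' @param models List of `single_feature_model`s.
#' @param ds The `peptide_set` they were trained on (training split labels
#'   define the baseline); if omitted, labels stored in the models are used.
#' @return The surviving models (possibly empty, with a warning).
#' @export
filter_by_accuracy <- function(models, ds = NULL) {
  labels <- if (!is.null(ds)) ds$label[ds$split == "train"] else models[[1L]]$labels
  baseline <- sum(labels == 0L) / length(labels)
  keep <- vapply(models, function(m) m$cv_metrics$ACC >= baseline, NA)
  if (!any(keep))
    warning("no model reaches the baseline accuracy ", signif(baseline, 4))
  models[keep]
}

#' Best subset from a selection trace
#'
#' The subset size with the highest validation AUC (ties: the smallest X).
#'
#' @param trace A `selection_trace`.
#' @return Character vector of member model keys at the best X.
#' @export
select_best <- function(trace) {
  stopifnot(inherits(trace, "selection_trace"))
  if (nrow(trace) == 0L) stop("empty selection trace")
  attr(trace, "member_sets")[[as.character(attr(trace, "best_X"))]]
}

#' Write a selection trace as TSV
#'
#' @param trace A `selection_trace`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(as.data.frame(trace), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
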