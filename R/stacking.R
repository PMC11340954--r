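#' Stack out-of-fold probabilities into a meta-feature matrix
#'
#' One column per single-feature model (in input order), one row per
#' training sample; labels and fold assignments are carried through so the
#' meta-classifier can reuse the base-level folds.
#'
#' @param models Non-empty list of `single_feature_model`s sharing one
#'   fold assignment and training split.
#' @return A `probability_matrix`: numeric matrix with attributes
#'   `model_keys`, `labels`, `folds`.
#' @export
build_probability_matrix <- function(models) {
  if (length(models) == 0L) stop("no single-feature models supplied")
  ref <- models[[1L]]
  for (m in models) {
    if (!identical(m$train_rows, ref$train_rows) ||
        !identical(m$fold_of_train, ref$fold_of_train))
      stop("models disagree on training rows or folds (model ", m$model_key, ")")
  }
  pm <- vapply(models, `[[`, numeric(length(ref$oof_probs)), "oof_probs")
  if (!is.matrix(pm)) pm <- matrix(pm, ncol = length(models))
  colnames(pm) <- vapply(models, `[[`, "", "model_key")
  if (any(pm < 0) || any(pm > 1)) stop("stacked probabilities outside [0, 1]")
  structure(pm, model_keys = colnames(pm), labels = ref$labels,
            folds = ref$fold_of_train, class = c("probability_matrix", "matrix"))
}

subset_pm <- function(pm, keys) {
  out <- pm[, keys, drop = FALSE]
  structure(out, model_keys = keys, labels = attr(pm, "labels"),
            folds = attr(pm, "folds"), class = class(pm))
}

#' Fit the meta-classifier on stacked probabilities
#'
#' Trains the second-level learner on the base models' out-of-fold
#' probability columns. Meta-level cross-validation reuses the base fold
#' assignment: for each fold the meta learner is fit on the remaining
#' folds' rows and predicts the held-out rows, giving OOF meta
#' probabilities from which the MCC-optimal decision threshold and the
#' validation metrics are derived. The final meta model is refit on all
#' rows; for the logistic-regression meta-classifier the weight vector
#' (whose absolute values are the AWCLR importances) is exposed.
#'
#' @param pm A `probability_matrix` (optionally column-subset).
#' @param meta_name One of `"LR"`, `"SVM"`, `"LGBM"`, `"XGB"`, `"RF"`,
#'   `"NB"`, `"KN"` (default `"LR"`).
#' @param seed Integer seed.
#' @return A `meta_model` with elements `meta_name`, `model_keys`,
#'   `threshold`, `oof_probs`, `cv_metrics`, `fit` and, for LR,
#'   `coefficients` (intercept first).
#' @export
fit_meta <- function(pm, meta_name = "LR", seed = 42L) {
  stopifnot(inherits(pm, "probability_matrix"))
  meta_name <- toupper(meta_name)
  if (!meta_name %in% CLASSICAL_CLASSIFIERS)
    stop("unsupported meta-classifier '", meta_name, "'; choose one of: ",
         paste(CLASSICAL_CLASSIFIERS, collapse = ", "))
  x <- unclass(pm)
  attr(x, "model_keys") <- NULL; attr(x, "labels") <- NULL; attr(x, "folds") <- NULL
  labels <- attr(pm, "labels"); folds <- attr(pm, "folds")
  if (length(unique(labels)) < 2L) stop("both classes required")
  oof <- rep(NA_real_, nrow(x))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fit_f <- fit_classifier(meta_name, x[tr, , drop = FALSE], labels[tr],
                            seed = as.integer(seed) + f, scale_features = FALSE)
    oof[!tr] <- predict_classifier(fit_f, x[!tr, , drop = FALSE])
  }
  fit <- fit_classifier(meta_name, x, labels, seed = as.integer(seed),
                        scale_features = FALSE)
  threshold <- mcc_optimal_threshold(labels, oof)
  coefs <- NULL
  if (meta_name == "LR") {
    co <- ridge_lr_coefs(fit$fit)
    names(co) <- c("(Intercept)", attr(pm, "model_keys")[fit$keep])
    # prune-dropped constant columns keep a zero weight for completeness
    full <- stats::setNames(numeric(ncol(x) + 1L),
                            c("(Intercept)", attr(pm, "model_keys")))
    full[names(co)] <- co
    coefs <- full
  }
  structure(list(
    meta_name = meta_name, model_keys = attr(pm, "model_keys"),
    fit = fit, coefficients = coefs, threshold = threshold,
    oof_probs = oof, labels = labels,
    cv_metrics = evaluate_probs(labels, oof, threshold)
  ), class = "meta_model")
}

#' @export
print.meta_model <- function(x, ...) {
  cat(sprintf("meta-classifier %s over %d base models: CV AUC %.3f, MCC %.3f (threshold %.4f)\n",
              x$meta_name, length(x$model_keys), x$cv_metrics$AUC,
              x$cv_metrics$MCC, x$threshold))
  invisible(x)
}

#' Absolute logistic-regression weights (AWCLR)
#'
#' The importance of each stacked single-feature model: the absolute value
#' of its weight coefficient in the logistic-regression meta-classifier
#' (intercept excluded).
#'
#' @param meta A `meta_model` with `meta_name == "LR"`.
#' @return Named numeric vector, one value per member model.
#' @export
extract_awclr <- function(meta) {
  stopifnot(inherits(meta, "meta_model"))
  if (meta$meta_name != "LR")
    stop("AWCLR is defined only for the LR meta-classifier")
  abs(meta$coefficients[-1L])
}

#' Predict with a stacked meta-classifier
#'
#' Runs each member single-feature model's refit classifier on the new
#' peptides, stacks the resulting probabilities in member order, applies
#' the meta-classifier and calls peptides positive at the stored
#' MCC-optimal threshold.
#'
#' @param meta A `meta_model`.
#' @param models List of `single_feature_model`s containing at least the
#'   members of `meta` (matched by model key).
#' @param features Named list mapping each member's encoding feature matrix
#'   for the new peptides; names are model keys (or a single matrix shared
#'   by all members).
#' @return Data frame with columns `probability` and `call`.
#' @export
predict_meta <- function(meta, models, features) {
  stopifnot(inherits(meta, "meta_model"))
  keys <- vapply(models, `[[`, "", "model_key")
  missing_keys <- setdiff(meta$model_keys, keys)
  if (length(missing_keys))
    stop("member model(s) missing: ", paste(missing_keys, collapse = ", "))
  cols <- lapply(meta$model_keys, function(k) {
    m <- models[[which(keys == k)[1L]]]
    f <- if (is.list(features) && !is.matrix(features)) features[[k]] else features
    if (is.null(f)) stop("no features supplied for member ", k)
    predict_single(m, f)
  })
  x <- do.call(cbind, cols)
  colnames(x) <- meta$model_keys
  prob <- predict_classifier(meta$fit, x)
  data.frame(probability = prob,
             call = as.integer(prob >= meta$threshold))
}
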