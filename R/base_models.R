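CLASSICAL_CLASSIFIERS <- c("RF", "XGB", "LGBM", "SVM", "KN", "NB", "LR")
DEEP_CLASSIFIERS <- c("TX", "CNN", "BLSTM")
# Classifiers whose features are standardized (fit on training folds only).
SCALED_CLASSIFIERS <- c("SVM", "LR", "KN")

CLASSICAL_ENCODINGS <- c("AAC", "DPC", "TPC", "PAAC", "CKSAAP", "GAAC",
                         "GDPC", "GTPC", "CTRIAD", "CTDC", "CTDT", "CTDD",
                         "EAAC", "AAINDEX", "BLOSUM62", "ZSCALE", "ESM2",
                         "W2V_1", "W2V_2", "W2V_3", "W2V_4")
DEEP_ENCODINGS <- c("BE", "NN", "ESM2", "W2V_1", "W2V_2", "W2V_3", "W2V_4")

#' Describe a base classifier
#'
#' @param name One of `"RF"`, `"XGB"`, `"LGBM"`, `"SVM"`, `"KN"`, `"NB"`,
#'   `"LR"` (deep names `"TX"`, `"CNN"`, `"BLSTM"` are reserved for the
#'   optional deep plugin).
#' @param params Named list of hyperparameters overriding the defaults.
#' @param seed Integer seed used for every stochastic step of the fit.
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(name, params = list(), seed = 42L) {
  name <- toupper(name)
  if (!name %in% c(CLASSICAL_CLASSIFIERS, DEEP_CLASSIFIERS))
    stop("unknown classifier '", name, "'")
  structure(list(name = name, params = params, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' The default 168-cell model grid
#'
#' Seven classical classifiers crossed with 21 fixed-vector encodings plus
#' three deep classifiers crossed with 7 sequence encodings: 147 + 21 = 168
#' classifier-encoding cells. Deep cells are enumerated for census and
#' bookkeeping but the bundled training path is classical-only, so they are
#' skipped unless a deep-learning plugin provides their backends.
#'
#' @param include_deep Keep the 21 deep cells (default TRUE).
#' @param drop_encodings Encodings to remove from both halves of the grid.
#' @return Data frame with columns `classifier`, `encoding`, `kind`,
#'   `model_key`.
#' @export
default_grid <- function(include_deep = TRUE, drop_encodings = character(0)) {
  drop_encodings <- toupper(drop_encodings)
  cls <- expand.grid(classifier = CLASSICAL_CLASSIFIERS,
                     encoding = setdiff(CLASSICAL_ENCODINGS, drop_encodings),
                     stringsAsFactors = FALSE)
  cls$kind <- "classical"
  grid <- cls
  if (include_deep) {
    dp <- expand.grid(classifier = DEEP_CLASSIFIERS,
                      encoding = setdiff(DEEP_ENCODINGS, drop_encodings),
                      stringsAsFactors = FALSE)
    dp$kind <- "deep"
    grid <- rbind(cls, dp)
  }
  grid$model_key <- paste0(grid$classifier, "-", grid$encoding)
  grid[order(grid$kind, grid$classifier, grid$encoding), ]
}

default_hyperparams <- function(name) {
  switch(name,
    RF = list(num_trees = 300L, min_node_size = 1L),
    XGB = list(nrounds = 100L, max_depth = 4L, eta = 0.1,
               tree_method = "exact"),
    LGBM = list(nrounds = 100L, eta = 0.1, max_leaves = 31L,
                tree_method = "hist", grow_policy = "lossguide"),
    SVM = list(kernel = "radial", cost = 1),
    KN = list(k = 5L),
    NB = list(var_floor = 1e-6),
    LR = list(lambda = NULL),  # NULL -> 1/n at fit time
    stop("no hyperparameter defaults for ", name))
}

# Fit one classifier on a numeric feature matrix. Handles per-fit column
# pruning (zero variance) and optional standardization so that every
# backend honours the probability contract.
fit_classifier <- function(name, x, y, params = list(), seed = 42L,
                           scale_features = name %in% SCALED_CLASSIFIERS) {
  stopifnot(is.matrix(x), length(y) == nrow(x))
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("degenerate single-class training set")
  p <- utils::modifyList(default_hyperparams(name), params)
  keep <- seq_len(ncol(x))
  center <- NULL; scl <- NULL
  if (name %in% c(SCALED_CLASSIFIERS, "NB")) {
    v <- apply(x, 2L, stats::var)
    if (any(v > 1e-12)) keep <- which(v > 1e-12)
    x <- x[, keep, drop = FALSE]
  }
  if (scale_features) {
    center <- colMeans(x)
    scl <- apply(x, 2L, stats::sd)
    scl[scl < 1e-12] <- 1
    x <- scale(x, center = center, scale = scl)
  }
  yf <- factor(y, levels = c(0L, 1L))
  rng <- local_rng(seed)
  fit <- switch(name,
    RF = ranger::ranger(x = x, y = yf, probability = TRUE,
                        num.trees = p$num_trees, min.node.size = p$min_node_size,
                        seed = seed, num.threads = 1L),
    XGB = ,
    LGBM = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = p$eta,
                    max_depth = if (name == "LGBM") 0L else p$max_depth,
                    tree_method = p$tree_method,
                    grow_policy = if (name == "LGBM") p$grow_policy else "depthwise",
                    max_leaves = if (name == "LGBM") p$max_leaves else 0L,
                    nthread = 1L, seed = seed),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1L),
      nrounds = p$nrounds, verbose = 0L),
    SVM = e1071::svm(x = x, y = yf, probability = TRUE, kernel = p$kernel,
                     cost = p$cost, scale = FALSE),
    KN = list(x = x, y = yf, k = p$k),
    NB = floor_nb_variance(e1071::naiveBayes(x = as.data.frame(x), y = yf),
                           p$var_floor),
    LR = fit_ridge_lr(x, y, lambda = p$lambda),
    stop("classifier '", name, "' has no classical backend (deep plugin not installed)"))
  structure(list(name = name, fit = fit, params = p, keep = keep,
                 center = center, scale = scl, n_features = length(keep),
                 backend = backend_name(name)),
            class = "stackpep_classifier")
}

backend_name <- function(name) {
  switch(name,
    RF = "ranger", XGB = "xgboost", LGBM = "xgboost-hist-lossguide",
    SVM = "e1071", KN = "class", NB = "e1071", LR = "glmnet-ridge", name)
}

floor_nb_variance <- function(fit, var_floor) {
  fit$tables <- lapply(fit$tables, function(tb) {
    tb[, 2L][tb[, 2L] < var_floor] <- var_floor
    tb
  })
  fit
}

# Ridge-penalized logistic regression via glmnet (alpha = 0). glmnet needs
# at least two columns, so single-column designs get a zero pad whose
# coefficient is discarded.
fit_ridge_lr <- function(x, y, lambda = NULL) {
  if (is.null(lambda)) lambda <- 1 / nrow(x)
  padded <- ncol(x) == 1L
  if (padded) x <- cbind(x, .pad = 0)
  fit <- glmnet::glmnet(x, factor(y, levels = c(0L, 1L)), family = "binomial",
                        alpha = 0, lambda = lambda, standardize = FALSE,
                        thresh = 1e-12, maxit = 1e6)
  structure(list(fit = fit, lambda = lambda, padded = padded),
            class = "ridge_lr")
}

predict_ridge_lr <- function(object, x) {
  if (object$padded) x <- cbind(x, .pad = 0)
  as.numeric(stats::predict(object$fit, newx = x, type = "response",
                            s = object$lambda))
}

ridge_lr_coefs <- function(object) {
  co <- as.matrix(stats::coef(object$fit, s = object$lambda))[, 1L]
  if (object$padded) co <- co[names(co) != ".pad"]
  co
}

# Positive-class probability from a fitted stackpep_classifier.
predict_classifier <- function(model, x) {
  stopifnot(inherits(model, "stackpep_classifier"), is.matrix(x))
  x <- x[, model$keep, drop = FALSE]
  if (!is.null(model$center))
    x <- scale(x, center = model$center, scale = model$scale)
  probs <- switch(model$name,
    RF = stats::predict(model$fit, data = x, num.threads = 1L)$predictions[, "1"],
    XGB = ,
    LGBM = stats::predict(model$fit, xgboost::xgb.DMatrix(x, nthread = 1L)),
    SVM = {
      pr <- stats::predict(model$fit, x, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    KN = {
      pred <- class::knn(model$fit$x, x, cl = model$fit$y, k = model$fit$k,
                         prob = TRUE, use.all = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "1", win, 1 - win)
    },
    NB = stats::predict(model$fit, as.data.frame(x), type = "raw")[, "1"],
    LR = predict_ridge_lr(model$fit, x))
  probs <- as.numeric(probs)
  pmin(pmax(probs, 0), 1)
}

#' Train one single-feature model with out-of-fold cross-validation
#'
#' Fits the classifier once per fold on the complementary folds, predicts
#' the held-out fold, concatenates the fold predictions into the
#' out-of-fold (OOF) probability vector, computes cross-validated metrics
#' at the MCC-optimal threshold, and refits on the full training split for
#' test-time prediction.
#'
#' @param ds A `peptide_set` with `split` and `fold` assigned.
#' @param features Either an `encoding_spec` (or encoding name), or a
#'   pre-computed numeric feature matrix aligned to the rows of `ds`.
#' @param clf A `classifier_spec` (or classifier name).
#' @param model_key Optional identifier; defaults to
#'   `"CLASSIFIER-ENCODING"`.
#' @return A `single_feature_model`: OOF probabilities aligned to the
#'   training rows, per-fold fit provenance, CV metrics and the refit
#'   full-training model.
#' @export
train_single <- function(ds, features, clf, model_key = NULL) {
  if (is.character(clf)) clf <- classifier_spec(clf)
  enc_name <- "CUSTOM"
  if (is.character(features)) features <- encoding_spec(features)
  if (inherits(features, "encoding_spec")) {
    enc_name <- features$name
    features <- encode_peptides(ds, features)
  }
  stopifnot(is.matrix(features), nrow(features) == nrow(ds))
  if (any(!is.finite(features)))
    stop("non-finite features supplied to classifier (encoding ", enc_name, ")")
  if (is.null(model_key)) model_key <- paste0(clf$name, "-", enc_name)
  train_rows <- which(ds$split == "train")
  if (length(train_rows) == 0L) stop("dataset has no training split")
  folds <- ds$fold[train_rows]
  if (any(is.na(folds))) stop("training rows lack fold assignments")
  labels <- ds$label[train_rows]
  fold_ids <- sort(unique(folds))
  oof <- rep(NA_real_, length(train_rows))
  fold_models <- list()
  for (f in fold_ids) {
    tr <- train_rows[folds != f]
    va <- train_rows[folds == f]
    fit <- fit_classifier(clf$name, features[tr, , drop = FALSE],
                          ds$label[tr], clf$params,
                          seed = clf$seed + f)
    oof[match(va, train_rows)] <- predict_classifier(fit, features[va, , drop = FALSE])
    fold_models[[as.character(f)]] <- list(fold = f, fit = fit,
                                           train_rows = tr, holdout_rows = va)
  }
  if (anyNA(oof)) stop("OOF construction left uncovered training samples")
  refit <- fit_classifier(clf$name, features[train_rows, , drop = FALSE],
                          labels, clf$params, seed = clf$seed)
  structure(list(
    model_key = model_key, encoding = enc_name, classifier = clf,
    train_rows = train_rows, fold_of_train = folds, labels = labels,
    oof_probs = oof, fold_models = fold_models, refit = refit,
    cv_metrics = evaluate_probs(labels, oof),
    backend = refit$backend
  ), class = "single_feature_model")
}

#' @export
print.single_feature_model <- function(x, ...) {
  cat(sprintf("single-feature model %s (backend %s): CV AUC %.3f, ACC %.3f, MCC %.3f\n",
              x$model_key, x$backend, x$cv_metrics$AUC, x$cv_metrics$ACC,
              x$cv_metrics$MCC))
  invisible(x)
}

#' Predict probabilities from a refit single-feature model
#'
#' @param model A `single_feature_model`.
#' @param features Feature matrix for the new peptides, with the same
#'   columns used at training time.
#' @return Probability vector in `[0, 1]` aligned to the rows of
#'   `features`.
#' @export
predict_single <- function(model, features) {
  stopifnot(inherits(model, "single_feature_model"), is.matrix(features))
  if (ncol(features) != length(model$refit$keep) &&
      ncol(features) < max(model$refit$keep))
    stop("feature dimension mismatch for ", model$model_key,
         ": got ", ncol(features))
  predict_classifier(model$refit, features)
}

#' Rank single-feature models by cross-validated AUC
#'
#' Descending AUC; ties broken by lexicographic model key.
#'
#' @param models List of `single_feature_model`s.
#' @return Data frame (`model_key`, `auc`) in rank order.
#' @export
rank_models_by_auc <- function(models) {
  df <- data.frame(
    model_key = vapply(models, `[[`, "", "model_key"),
    auc = vapply(models, function(m) m$cv_metrics$AUC, 0),
    stringsAsFactors = FALSE
  )
  df[order(-df$auc, df$model_key), , drop = FALSE]
}

#' Audit out-of-fold integrity of a single-feature model
#'
#' Verifies that every training sample's stacked probability was produced
#' by the fold model that held that sample out, i.e. the sample is in that
#' fold model's holdout set and absent from its training rows.
#'
#' @param model A `single_feature_model`.
#' @return TRUE if the audit passes; otherwise an error describing the
#'   first violation.
#' @export
audit_oof <- function(model) {
  stopifnot(inherits(model, "single_feature_model"))
  for (i in seq_along(model$train_rows)) {
    row <- model$train_rows[i]
    fm <- model$fold_models[[as.character(model$fold_of_train[i])]]
    if (is.null(fm)) stop("no fold model for fold ", model$fold_of_train[i])
    if (row %in% fm$train_rows)
      stop("leakage: sample row ", row, " trained its own fold model")
    if (!row %in% fm$holdout_rows)
      stop("sample row ", row, " missing from its fold's holdout set")
  }
  TRUE
}
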