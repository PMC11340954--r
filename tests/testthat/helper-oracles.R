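# Independent reference implementations used as oracles. These deliberately
# avoid the package's own code paths (and glmnet) so that agreement is a
# two-route check, not a tautology.

# Ridge-penalized logistic regression by hand-rolled IRLS:
# minimize (1/n) sum nll + lambda/2 ||beta||^2, intercept unpenalized.
ref_ridge_lr <- function(x, y, lambda = 1 / nrow(x), tol = 1e-10, max_iter = 200) {
  x1 <- cbind(1, x)
  p <- ncol(x1)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- rep(0, p)
  n <- nrow(x1)
  for (it in seq_len(max_iter)) {
    eta <- drop(x1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    g <- drop(crossprod(x1, mu - y)) / n + pen %*% beta
    H <- crossprod(x1 * w, x1) / n + pen
    step <- solve(H, g)
    beta <- beta - step
    if (max(abs(step)) < tol) break
  }
  drop(beta)
}

# Naive sequential-deletion loop with iteratively recomputed absolute LR
# weights: returns the member sets at every size n..1 (list) and the
# deletion order. Ties on the minimum weight delete the lexicographically
# last column name.
ref_sdiwc <- function(x, y, lambda = 1 / nrow(x)) {
  remaining <- colnames(x)
  sets <- list()
  deleted <- character(0)
  while (length(remaining) >= 1L) {
    sets[[as.character(length(remaining))]] <- remaining
    if (length(remaining) == 1L) break
    beta <- ref_ridge_lr(x[, remaining, drop = FALSE], y, lambda)
    aw <- abs(beta[-1L])
    names(aw) <- remaining
    worst <- names(aw)[aw == min(aw)]
    drop_key <- sort(worst)[length(worst)]
    deleted <- c(deleted, drop_key)
    remaining <- setdiff(remaining, drop_key)
  }
  list(sets = sets, deleted = deleted)
}

# AUC by exhaustive positive/negative pair counting (ties count one half).
ref_auc_paircount <- function(labels, probs) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# MCC from confusion counts, written independently of the package.
ref_mcc <- function(labels, pred) {
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  den <- sqrt(as.numeric(tp + fp)) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / den
}

# Best MCC over a dense threshold grid.
ref_best_mcc_grid <- function(labels, probs, by = 1e-3) {
  best <- -Inf
  for (th in seq(0, 1, by = by)) {
    m <- ref_mcc(labels, as.integer(probs >= th))
    if (m > best) best <- m
  }
  best
}

# Labeled dataset with split and folds assigned, ready for train_single.
make_cv_ds <- function(n_pos = 40, n_neg = 160, seed = 1,
                       motifs = list(list(pattern = "WYKWH", prob = 0.9)),
                       n_folds = 5) {
  ds <- generate_peptides(synthetic_spec(n_pos = n_pos, n_neg = n_neg,
                                         motifs = motifs, seed = seed))
  ds <- stratified_split(ds, 0.2, seed = seed + 1)
  assign_folds(ds, n_folds, seed = seed + 2)
}

# Random probability-matrix toy: s signal columns correlated with labels,
# t pure-noise columns, wrapped as a probability_matrix via train-less
# construction (attributes set directly).
make_toy_pm <- function(n = 60, s = 2, t = 2, seed = 1, n_folds = 5) {
  set.seed(seed)
  n_pos <- round(n / 3)
  labels <- rep(c(1L, 0L), c(n_pos, n - n_pos))
  cols <- list()
  for (i in seq_len(s))
    cols[[paste0("SIG", i)]] <- pmin(pmax(labels * 0.4 + runif(n) * 0.6, 0), 1)
  for (i in seq_len(t))
    cols[[paste0("NOI", i)]] <- runif(n)
  x <- do.call(cbind, cols)
  folds <- rep_len(0:(n_folds - 1), n)
  structure(x, model_keys = colnames(x), labels = labels, folds = folds,
            class = c("probability_matrix", "matrix"))
}
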