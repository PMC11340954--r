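fit_two_detectors <- function(ds) {
  motifs <- attr(ds, "motifs")
  lapply(stats::setNames(motifs, paste0("LR-", motifs)), function(mo)
    train_single(ds, motif_count_features(ds, mo),
                 classifier_spec("LR", seed = 3),
                 model_key = paste0("LR-", mo)))
}

test_that("the probability matrix stacks OOF columns in model order", {
  ds <- make_cv_ds(n_pos = 20, n_neg = 60, seed = 17)
  models <- list(
    train_single(ds, "AAC", classifier_spec("LR", seed = 1)),
    train_single(ds, "GAAC", classifier_spec("NB", seed = 2)),
    train_single(ds, "CTDC", classifier_spec("LR", seed = 3))
  )
  pm <- build_probability_matrix(models)
  expect_equal(dim(pm), c(sum(ds$split == "train"), 3L))
  expect_equal(unname(pm[, 2]), models[[2]]$oof_probs)
  expect_equal(attr(pm, "model_keys"),
               c("LR-AAC", "NB-GAAC", "LR-CTDC"))
  expect_error(build_probability_matrix(list()), "no single-feature models")
})

test_that("the LR meta-classifier satisfies the log-odds identity", {
  pm <- make_toy_pm(n = 60, s = 2, t = 1, seed = 4)
  meta <- fit_meta(pm, "LR", seed = 9)
  x <- cbind(1, unclass(pm))
  p <- stackpep:::predict_classifier(meta$fit, unclass(pm))
  eta <- drop(x %*% meta$coefficients)
  expect_equal(log(p / (1 - p)), eta, tolerance = 1e-6)
})

test_that("meta fitting is deterministic, separable columns dominate, constants get zero weight", {
  n <- 60
  labels <- rep(c(1L, 0L), c(20, 40))
  x <- cbind(PERFECT = labels + 0.0, CONST = rep(0.5, n))
  pm <- structure(x, model_keys = colnames(x), labels = labels,
                  folds = rep_len(0:4, n),
                  class = c("probability_matrix", "matrix"))
  m1 <- fit_meta(pm, "LR", seed = 1)
  m2 <- fit_meta(pm, "LR", seed = 1)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_equal(m1$cv_metrics$AUC, 1.0)
  expect_gt(m1$coefficients["PERFECT"], 0)
  expect_equal(unname(m1$coefficients["CONST"]), 0)

  expect_error(fit_meta(pm, "GBM"), "unsupported meta-classifier")
})

test_that("AWCLR is the absolute weight vector without the intercept", {
  pm <- make_toy_pm(n = 50, s = 2, t = 2, seed = 6)
  meta <- fit_meta(pm, "LR", seed = 2)
  aw <- extract_awclr(meta)
  expect_equal(unname(aw), unname(abs(meta$coefficients[-1])))
  expect_named(aw, attr(pm, "model_keys"))
  nb <- fit_meta(pm, "NB", seed = 2)
  expect_error(extract_awclr(nb), "LR")
})

test_that("the stored threshold maximizes training MCC against an exhaustive scan", {
  pm <- make_toy_pm(n = 80, s = 2, t = 2, seed = 8)
  meta <- fit_meta(pm, "LR", seed = 3)
  labels <- attr(pm, "labels")
  ours <- confusion_metrics(labels, meta$oof_probs, meta$threshold)$MCC
  cand <- sort(unique(c(0, meta$oof_probs, 1)))
  best <- max(vapply(cand, function(th)
    ref_mcc(labels, as.integer(meta$oof_probs >= th)), 0))
  expect_equal(ours, best)
})

test_that("stacking complementary detectors dominates each single model", {
  wins <- 0L
  for (seed in 1:5) {
    ds <- make_complementary_signals(seed * 100, n_pos = 60, n_neg = 240)
    ds <- stratified_split(ds, 0.2, seed = seed)
    ds <- assign_folds(ds, 5, seed = seed + 1)
    models <- fit_two_detectors(ds)
    single_auc <- vapply(models, function(m) m$cv_metrics$AUC, 0)
    # each single-motif detector is informative but far from perfect
    expect_true(all(single_auc > 0.5 & single_auc < 1))
    meta <- fit_meta(build_probability_matrix(models), "LR", seed = seed)
    if (meta$cv_metrics$AUC >= max(single_auc) - 0.01) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("meta predictions are invariant to member order and respect the threshold", {
  ds <- make_cv_ds(n_pos = 20, n_neg = 60, seed = 33)
  feats <- encode_peptides(ds, "AAC")
  m1 <- train_single(ds, feats, classifier_spec("LR", seed = 1))
  m2 <- train_single(ds, feats, classifier_spec("NB", seed = 2))
  meta <- fit_meta(build_probability_matrix(list(m1, m2)), "LR", seed = 5)
  test_rows <- which(ds$split == "test")
  fx <- feats[test_rows, , drop = FALSE]
  pa <- predict_meta(meta, list(m1, m2), fx)
  pb <- predict_meta(meta, list(m2, m1), fx)
  expect_equal(pa, pb)
  expect_equal(pa$call, as.integer(pa$probability >= meta$threshold))
  expect_error(predict_meta(meta, list(m1), fx), "NB-CUSTOM")
})
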