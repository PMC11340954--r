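make_trained_set <- function(seed = 41, n_pos = 25, n_neg = 100,
                             encodings = c("AAC", "GAAC", "CTDC"),
                             classifiers = c("LR", "NB")) {
  ds <- make_cv_ds(n_pos = n_pos, n_neg = n_neg, seed = seed)
  models <- list()
  i <- 0L
  for (enc in encodings) for (clf in classifiers) {
    i <- i + 1L
    key <- paste0(clf, "-", enc)
    models[[key]] <- train_single(ds, enc, classifier_spec(clf, seed = seed + i),
                                  model_key = key)
  }
  list(ds = ds, models = models, pm = build_probability_matrix(models))
}

test_that("SAAUC and SAWC produce nested traces anchored at the full fit", {
  ts <- make_trained_set()
  for (trace in list(saauc(ts$models, ts$pm, seed = 1),
                     sawc(ts$models, ts$pm, seed = 1))) {
    expect_equal(nrow(trace), length(ts$models))
    sets <- attr(trace, "member_sets")
    for (X in seq_len(length(ts$models) - 1L))
      expect_true(all(sets[[as.character(X)]] %in% sets[[as.character(X + 1L)]]))
    # the full-size step equals a direct meta fit on all columns
    full <- fit_meta(ts$pm, "LR", seed = 1)
    expect_equal(trace$auc[trace$X == length(ts$models)],
                 full$cv_metrics$AUC)
  }
})

test_that("SAAUC adds models in CV-AUC rank order and SAWC in AWCLR order", {
  ts <- make_trained_set(seed = 43)
  tr_auc <- saauc(ts$models, ts$pm, seed = 2)
  expect_equal(attr(tr_auc, "member_sets")[["1"]],
               rank_models_by_auc(ts$models)$model_key[1])
  tr_aw <- sawc(ts$models, ts$pm, seed = 2)
  aw <- extract_awclr(fit_meta(ts$pm, "LR", seed = 2))
  expect_equal(attr(tr_aw, "member_sets")[["1"]],
               names(aw)[order(-aw, names(aw))][1])
})

test_that("SDIWC deletes exactly one minimum-AWCLR model per step", {
  ts <- make_trained_set(seed = 47)
  trace <- sdiwc(ts$models, ts$pm, seed = 3)
  n <- length(ts$models)
  expect_equal(nrow(trace), n)
  sets <- attr(trace, "member_sets")
  aws <- attr(trace, "awclr_steps")
  for (X in n:2) {
    cur <- sets[[as.character(X)]]
    nxt <- sets[[as.character(X - 1L)]]
    dropped <- setdiff(cur, nxt)
    expect_length(dropped, 1L)
    aw <- aws[[as.character(X)]]
    expect_equal(unname(aw[dropped]), min(aw))
  }
})

test_that("SDIWC agrees with a naive reimplementation built on reference IRLS", {
  for (cfg in list(list(n = 60, s = 2, t = 2, seed = 101),
                   list(n = 50, s = 3, t = 3, seed = 202),
                   list(n = 60, s = 1, t = 4, seed = 303))) {
    pm <- make_toy_pm(n = cfg$n, s = cfg$s, t = cfg$t, seed = cfg$seed)
    trace <- sdiwc(NULL, pm, seed = 1)
    ref <- ref_sdiwc(unclass(pm), attr(pm, "labels"))
    sets <- attr(trace, "member_sets")
    for (X in names(ref$sets))
      expect_setequal(sets[[X]], ref$sets[[X]])
    # exact deletion order
    n <- ncol(pm)
    ours_deleted <- vapply(n:2, function(X)
      setdiff(sets[[as.character(X)]], sets[[as.character(X - 1L)]]), "")
    expect_equal(ours_deleted, ref$deleted)
  }
})

test_that("SDIWC discards a pure-noise column early and retains signal columns", {
  noise_gone_early <- 0L
  signal_kept <- 0L
  for (seed in 1:10) {
    pm <- make_toy_pm(n = 60, s = 2, t = 1, seed = seed)
    trace <- sdiwc(NULL, pm, seed = seed)
    sets <- attr(trace, "member_sets")
    n <- ncol(pm)
    first_two <- c(setdiff(sets[[as.character(n)]], sets[[as.character(n - 1L)]]),
                   setdiff(sets[[as.character(n - 1L)]], sets[[as.character(n - 2L)]]))
    if (any(grepl("^NOI", first_two))) noise_gone_early <- noise_gone_early + 1L
    if (all(c("SIG1", "SIG2") %in% select_best(trace)))
      signal_kept <- signal_kept + 1L
  }
  expect_gte(noise_gone_early, 8L)
  expect_gte(signal_kept, 9L)
})

test_that("the accuracy pre-filter computes the majority baseline from the data", {
  ts <- make_trained_set(seed = 53)
  labels <- ts$ds$label[ts$ds$split == "train"]
  baseline <- sum(labels == 0) / length(labels)
  kept <- filter_by_accuracy(ts$models, ts$ds)
  accs <- vapply(ts$models, function(m) m$cv_metrics$ACC, 0)
  expect_equal(length(kept), sum(accs >= baseline))
  # balanced data -> baseline one half
  bal <- list(structure(list(model_key = "A", labels = rep(c(0L, 1L), 10),
                             cv_metrics = list(ACC = 0.6)),
                        class = "single_feature_model"),
              structure(list(model_key = "B", labels = rep(c(0L, 1L), 10),
                             cv_metrics = list(ACC = 0.4)),
                        class = "single_feature_model"))
  expect_length(filter_by_accuracy(bal), 1L)
  low <- bal[2]
  expect_warning(out <- filter_by_accuracy(low), "baseline")
  expect_length(out, 0L)
})

test_that("select_best applies the argmax rule with the smallest-X tie-break", {
  mk <- function(aucs) {
    steps <- lapply(seq_along(aucs), function(X)
      list(X = X, members = paste0("M", seq_len(X)), auc = aucs[X],
           mcc = 0, awclr = NULL))
    stackpep:::new_trace("SAAUC", steps)
  }
  expect_length(select_best(mk(c(0.7, 0.9, 0.85))), 2L)
  expect_length(select_best(mk(c(0.7, 0.9, 0.8, 0.8, 0.9))), 2L)
  expect_length(select_best(mk(c(0.5, 0.6, 0.7))), 3L)
  # plateau detector reports the start of a sustained near-maximum run
  tr <- mk(c(0.5, 0.899, 0.9, 0.9, 0.9))
  expect_equal(attr(tr, "plateau_X"), 2L)
})
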