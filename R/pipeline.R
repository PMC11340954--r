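#' Configure an end-to-end stacking run
#'
#' @param encodings Character vector of encoding names for the base grid
#'   (default a light composition set; `"default"` expands to the full
#'   classical encoding list).
#' @param classifiers Character vector of base classifier names.
#' @param meta_name Meta-classifier (default `"LR"`).
#' @param selection One of `"sdiwc"`, `"sawc"`, `"saauc"`, `"none"`.
#' @param acc_prefilter Drop base models below the majority-class baseline
#'   accuracy before selection (default FALSE).
#' @param test_fraction Held-out fraction per class (default 0.2).
#' @param n_folds Cross-validation folds (default 5).
#' @param w2v Parameters for any W2V_k encodings
#'   (`list(dim=, window=, epochs=, corpus=)`; corpus defaults to the
#'   training-split sequences).
#' @param esm2 Parameters for the ESM2 encoding
#'   (`list(provider=, dim=, cache_dir=)`).
#' @param seed Master seed; all per-stage seeds are derived from it.
#' @return A `run_config` list.
#' @export
run_config <- function(encodings = c("AAC", "DPC", "GAAC", "CTDC"),
                       classifiers = c("LR", "RF", "NB"),
                       meta_name = "LR", selection = "sdiwc",
                       acc_prefilter = FALSE, test_fraction = 0.2,
                       n_folds = 5L,
                       w2v = list(dim = 32L, window = 40L, epochs = 20L),
                       esm2 = list(provider = "hash", dim = 32L),
                       seed = 42L) {
  if (identical(encodings, "default")) encodings <- CLASSICAL_ENCODINGS
  selection <- match.arg(tolower(selection), c("sdiwc", "sawc", "saauc", "none"))
  structure(list(encodings = toupper(encodings),
                 classifiers = toupper(classifiers), meta_name = meta_name,
                 selection = selection, acc_prefilter = acc_prefilter,
                 test_fraction = test_fraction, n_folds = as.integer(n_folds),
                 w2v = w2v, esm2 = esm2, seed = as.integer(seed)),
            class = "run_config")
}

encode_all <- function(ds, config) {
  feats <- list()
  train_seqs <- ds$sequence[ds$split == "train"]
  L_max <- max(nchar(ds$sequence))
  for (enc in config$encodings) {
    spec <- if (grepl("^W2V_", enc)) {
      k <- as.integer(sub("W2V_", "", enc))
      corpus <- config$w2v$corpus %||% train_seqs
      model <- train_w2v(corpus, k = k, dim = config$w2v$dim %||% 32L,
                         window = config$w2v$window %||% 40L,
                         epochs = config$w2v$epochs %||% 20L,
                         seed = config$seed + 1000L + k)
      encoding_spec(enc, model = model)
    } else if (enc == "ESM2") {
      encoding_spec("ESM2", provider = config$esm2$provider %||% "hash",
                    dim = config$esm2$dim %||% 32L,
                    cache_dir = config$esm2$cache_dir)
    } else if (enc %in% c("BE", "EAAC", "BLOSUM62", "ZSCALE")) {
      encoding_spec(enc, L_max = L_max)
    } else encoding_spec(enc)
    feats[[enc]] <- encode_peptides(ds, spec)
  }
  feats
}

#' Run the full stacking workflow
#'
#' Split, fold assignment, feature encoding, base-model grid training with
#' out-of-fold probabilities, probability stacking, optional accuracy
#' pre-filter, base-model subset selection, final meta-classifier fit on
#' the selected members, and held-out evaluation at the training-derived
#' MCC-optimal threshold.
#'
#' @param ds A labeled `peptide_set` (splits/folds are assigned here).
#' @param config A `run_config`.
#' @param outdir Optional directory for the run manifest, metric tables
#'   and selection trace.
#' @return A `stackpep_fit` with the base models, probability matrix,
#'   selection trace, final meta model, test metrics and feature contexts.
#' @export
run_pipeline <- function(ds, config = run_config(), outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  ds <- stratified_split(ds, config$test_fraction, seed = config$seed)
  ds <- assign_folds(ds, config$n_folds, seed = config$seed + 1L)
  feats <- encode_all(ds, config)
  models <- list()
  cell <- 0L
  for (enc in config$encodings) {
    for (clf in config$classifiers) {
      cell <- cell + 1L
      key <- paste0(clf, "-", enc)
      models[[key]] <- train_single(
        ds, feats[[enc]],
        classifier_spec(clf, seed = config$seed + 10L * cell), model_key = key)
    }
  }
  pm <- build_probability_matrix(models)
  sel_models <- models
  if (config$acc_prefilter) {
    sel_models <- filter_by_accuracy(models, ds)
    if (length(sel_models) == 0L) sel_models <- models
    pm_sel <- subset_pm(pm, vapply(sel_models, `[[`, "", "model_key"))
  } else pm_sel <- pm
  trace <- NULL
  members <- attr(pm_sel, "model_keys")
  if (config$selection != "none" && length(sel_models) >= 2L) {
    trace <- switch(config$selection,
      sdiwc = sdiwc(sel_models, pm_sel, seed = config$seed),
      sawc = sawc(sel_models, pm_sel, seed = config$seed),
      saauc = saauc(sel_models, pm_sel, config$meta_name, seed = config$seed))
    members <- select_best(trace)
  }
  meta <- fit_meta(subset_pm(pm, members), config$meta_name, seed = config$seed)
  test_rows <- which(ds$split == "test")
  test_feats <- lapply(feats, function(f) f[test_rows, , drop = FALSE])
  feat_of_key <- function(k) test_feats[[sub("^[A-Z]+-", "", k)]]
  test_pred <- predict_meta(meta, models,
                            stats::setNames(lapply(members, feat_of_key), members))
  test_metrics <- evaluate_probs(ds$label[test_rows], test_pred$probability,
                                 threshold = meta$threshold)
  fit <- structure(list(
    config = config, dataset = ds, features = feats, models = models,
    probability_matrix = pm, trace = trace, members = members, meta = meta,
    test_metrics = test_metrics
  ), class = "stackpep_fit")
  if (!is.null(outdir)) write_run(fit, outdir)
  fit
}

#' @export
print.stackpep_fit <- function(x, ...) {
  cat(sprintf("stacked peptide classifier: %d base models, %d selected (%s), meta %s\n",
              length(x$models), length(x$members), x$config$selection,
              x$meta$meta_name))
  cat("  validation: "); print(x$meta$cv_metrics)
  cat("  test:       "); print(x$test_metrics)
  invisible(x)
}

#' Predict new peptides with a fitted stacking pipeline
#'
#' Encodes the new sequences with the member models' encodings (reusing
#' the training-time contexts: padded lengths, embedding models) and
#' applies the meta-classifier at the stored threshold.
#'
#' @param fit A `stackpep_fit`.
#' @param ds A `peptide_set` or character vector of sequences.
#' @return Data frame `id`, `probability`, `call`.
#' @export
predict_pipeline <- function(fit, ds) {
  stopifnot(inherits(fit, "stackpep_fit"))
  if (!is.data.frame(ds)) ds <- peptide_set(sequence = ds)
  enc_names <- unique(sub("^[A-Z]+-", "", fit$members))
  feats <- list()
  for (enc in enc_names) {
    spec <- attr(fit$features[[enc]], "encoding")
    feats[[enc]] <- encode_peptides(ds, spec)
  }
  pred <- predict_meta(fit$meta, fit$models,
                       stats::setNames(lapply(sub("^[A-Z]+-", "", fit$members),
                                              function(e) feats[[e]]),
                                       fit$members))
  cbind(data.frame(id = ds$id, stringsAsFactors = FALSE), pred)
}

metric_row <- function(m) {
  data.frame(SEN = m$SEN, SPE = m$SPE, PRE = m$PRE, ACC = m$ACC,
             MCC = m$MCC, AUC = m$AUC, AUPRC = m$AUPRC)
}

#' Base-model metric table
#'
#' One row per single-feature model with its cross-validated metrics, in
#' the standard SEN/SPE/PRE/ACC/MCC/AUC/AUPRC column layout.
#'
#' @param models List of `single_feature_model`s (or a `stackpep_fit`).
#' @return Data frame.
#' @export
model_metric_table <- function(models) {
  if (inherits(models, "stackpep_fit")) models <- models$models
  do.call(rbind, lapply(models, function(m)
    cbind(data.frame(model_key = m$model_key, backend = m$backend,
                     stringsAsFactors = FALSE),
          metric_row(m$cv_metrics))))
}

write_run <- function(fit, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tab <- model_metric_table(fit)
  utils::write.table(tab, file.path(outdir, "base_models.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(fit$trace)) write_trace(fit$trace, file.path(outdir, "trace.tsv"))
  utils::write.table(cbind(dataset = "validation", metric_row(fit$meta$cv_metrics)) |>
                       rbind(cbind(dataset = "test", metric_row(fit$test_metrics))),
                     file.path(outdir, "meta_metrics.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest <- list(
    seed = fit$config$seed,
    encodings = fit$config$encodings,
    classifiers = fit$config$classifiers,
    meta_name = fit$meta$meta_name,
    selection = fit$config$selection,
    members = fit$members,
    threshold = fit$meta$threshold,
    coefficients = as.list(fit$meta$coefficients),
    n_train = sum(fit$dataset$split == "train"),
    n_test = sum(fit$dataset$split == "test"),
    files = c("base_models.tsv", "meta_metrics.tsv",
              if (!is.null(fit$trace)) "trace.tsv")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' Train from files (command-line entry)
#'
#' Thin wrapper used by the `stackpep` command-line script: reads a FASTA
#' or CSV dataset, runs [run_pipeline()] and writes the run artifacts.
#'
#' @param data_path FASTA (labels in headers) or CSV dataset.
#' @param outdir Output directory.
#' @param config A `run_config`.
#' @return The `stackpep_fit`, invisibly.
#' @export
cmd_train <- function(data_path, outdir, config = run_config()) {
  ds <- if (grepl("\\.(fa|fasta|fna)$", data_path, ignore.case = TRUE))
    read_fasta(data_path) else read_csv_dataset(data_path)
  if (any(is.na(ds$label))) stop("training data must be fully labeled")
  fit <- run_pipeline(ds, config, outdir = outdir)
  saveRDS(fit, file.path(outdir, "fit.rds"))
  invisible(fit)
}

#' Predict from files (command-line entry)
#'
#' @param run_dir Directory written by [cmd_train()].
#' @param fasta_path Peptides to score.
#' @param out_path Output TSV (`id`, `probability`, `call`).
#' @return The prediction data frame, invisibly.
#' @export
cmd_predict <- function(run_dir, fasta_path, out_path = stdout()) {
  fit_file <- file.path(run_dir, "fit.rds")
  if (!file.exists(fit_file)) stop("no trained run found in ", run_dir)
  fit <- readRDS(fit_file)
  ds <- read_fasta(fasta_path)
  pred <- predict_pipeline(fit, ds)
  utils::write.table(pred, out_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(pred)
}
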