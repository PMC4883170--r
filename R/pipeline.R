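#' End-to-end healthy-versus-ictal classification pipeline
#'
#' Runs the full procedure on an EEG dataset: hierarchical simple random
#' sampling and feature extraction ([build_feature_matrix()]), a
#' stratified train/test split, sequential feature selection on the
#' training portion only ([select_features()], applied unchanged to the
#' test portion to avoid leakage), LS-SVM training ([lssvm()]) and
#' test-set scoring ([classification_metrics()]).
#'
#' @param data An `"eeg_dataset"` (list of [eeg_record()]) or a prebuilt
#'   [feature_matrix()].
#' @param design A [sampling_design()].
#' @param spec A [feature_spec()].
#' @param criterion An [sfs_criterion()]; `NULL` skips feature selection.
#' @param gamma,sigma2,standardize Passed to [lssvm()].  The pipeline
#'   z-scores features by default: the subsample statistics live on the raw
#'   ADC amplitude scale (hundreds of units), so with \eqn{\sigma^2} of
#'   order 1 the RBF kernel between unscaled rows underflows to the
#'   identity matrix and the classifier degenerates to its bias term.
#' @param train_fraction Passed to [stratified_split()].
#' @param folds If >= 2, stratified k-fold cross-validation is run instead
#'   of a single split and per-fold metrics are returned.
#' @param seed Master seed governing sampling, the split and fold
#'   assignment.
#' @return Object of class `"srs_sfs_fit"`: the test-set
#'   `metrics` (mean across folds when cross-validating), the `sfs`
#'   selection, the fitted `model` (last fold), and the configuration.
#' @examples
#' ds <- generate_synthetic_dataset(synthetic_config(records_per_class = 6,
#'                                                   record_length = 512))
#' fit <- srs_sfs_classify(ds, sampling_design(512, samples_per_record = 4,
#'                                             subsamples_per_sample = 2))
#' fit$metrics$accuracy
#' @export
srs_sfs_classify <- function(data, design = sampling_design(),
                             spec = feature_spec(),
                             criterion = sfs_criterion("mean", "ge"),
                             gamma = 10, sigma2 = 1, standardize = TRUE,
                             train_fraction = 0.5, folds = NULL,
                             seed = 1L) {
  fm <- if (inherits(data, "feature_matrix")) data
        else build_feature_matrix(data, design, spec, seed = seed)

  run_one <- function(train, test) {
    if (!is.null(criterion)) {
      sfs <- select_features(train, criterion)
      train <- project(train, sfs)
      test <- project(test, sfs)
    } else sfs <- NULL
    model <- lssvm(train$x, train$label, gamma = gamma, sigma2 = sigma2,
                   standardize = standardize)
    pred <- predict(model, test$x)
    rep <- classification_metrics(confusion(test$label, pred))
    list(sfs = sfs, model = model, metrics = rep)
  }

  config <- list(design = design, spec = spec, criterion = criterion,
                 gamma = gamma, sigma2 = sigma2, standardize = standardize,
                 train_fraction = train_fraction, folds = folds, seed = seed)

  if (!is.null(folds) && folds >= 2L) {
    assign_fold <- with_local_seed(substream_seed(seed, 7L, 1L), {
      f <- integer(nrow(fm$x))
      for (cl in unique(fm$label)) {
        rows <- which(fm$label == cl)
        f[rows] <- sample(rep_len(seq_len(folds), length(rows)))
      }
      f
    })
    sub <- function(i) feature_matrix(fm$x[i, , drop = FALSE], fm$label[i],
                                      fm$provenance[i, , drop = FALSE])
    runs <- lapply(seq_len(folds), function(k)
      run_one(sub(which(assign_fold != k)), sub(which(assign_fold == k))))
    fold_metrics <- lapply(runs, `[[`, "metrics")
    avg <- function(f) mean(vapply(fold_metrics, `[[`, numeric(1), f))
    tot <- Reduce(function(a, b) confusion_counts(a$tp + b$tp, a$tn + b$tn,
                                                  a$fp + b$fp, a$fn + b$fn),
                  lapply(fold_metrics, `[[`, "counts"))
    metrics <- classification_metrics(tot, config = config)
    last <- runs[[folds]]
    out <- list(metrics = metrics, fold_metrics = fold_metrics,
                sfs = last$sfs, model = last$model, feature_matrix = fm,
                config = config)
  } else {
    split <- stratified_split(fm, train_fraction,
                              seed = substream_seed(seed, 9L, 1L))
    run <- run_one(split$train, split$test)
    run$metrics$config <- config
    out <- list(metrics = run$metrics, sfs = run$sfs, model = run$model,
                split = split[c("train_idx", "test_idx")],
                feature_matrix = fm, config = config)
  }
  class(out) <- "srs_sfs_fit"
  out
}

#' @export
print.srs_sfs_fit <- function(x, ...) {
  cat("SRS + SFS + LS-SVM classification\n")
  cat(sprintf("  feature matrix : %d x %d\n", nrow(x$feature_matrix$x),
              ncol(x$feature_matrix$x)))
  if (!is.null(x$sfs))
    cat(sprintf("  SFS            : kept %d of %d columns (delta = %.6g)\n",
                length(x$sfs$selected), x$sfs$n_features, x$sfs$delta))
  cat(sprintf("  LS-SVM         : gamma = %g, sigma2 = %g\n",
              x$config$gamma, x$config$sigma2))
  if (!is.null(x$fold_metrics))
    cat(sprintf("  evaluation     : %d-fold cross-validation\n",
                x$config$folds))
  print(x$metrics)
  invisible(x)
}

#' @export
summary.srs_sfs_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$sfs)) {
    cat("Selected columns:\n ")
    cat(strwrap(paste(object$sfs$column_names[object$sfs$selected],
                      collapse = ", "), width = 75, prefix = " "),
        sep = "\n")
  }
  invisible(object)
}

#' @export
plot.srs_sfs_fit <- function(x, ...) plot(x$model, ...)
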