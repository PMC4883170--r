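#' Stratified train/test split of a feature matrix
#'
#' Splits rows into a training and a testing portion while preserving the
#' per-class proportions (within rounding).  The split is deterministic
#' given `seed`.
#'
#' @param fm A [feature_matrix()].
#' @param train_fraction Fraction of each class assigned to training,
#'   strictly in (0, 1).  Default 0.5 (an even division into two groups).
#' @param seed Optional integer seed.
#' @return List with elements `train` and `test` (feature matrices) and
#'   the row indices `train_idx`, `test_idx`.
#' @export
stratified_split <- function(fm, train_fraction = 0.5, seed = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("'train_fraction' must lie strictly between 0 and 1",
         call. = FALSE)
  classes <- unique(fm$label)
  if (length(classes) < 2L)
    stop("both classes must be present", call. = FALSE)
  if (any(table(fm$label) < 2L))
    stop("every class needs at least 2 rows to split", call. = FALSE)
  train_idx <- with_local_seed(seed, {
    unlist(lapply(classes, function(cl) {
      rows <- which(fm$label == cl)
      n_tr <- max(1L, min(length(rows) - 1L,
                          as.integer(round(train_fraction * length(rows)))))
      sort(rows[sample.int(length(rows), n_tr)])
    }))
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(nrow(fm$x)), train_idx)
  subset_fm <- function(i)
    feature_matrix(fm$x[i, , drop = FALSE], fm$label[i],
                   fm$provenance[i, , drop = FALSE])
  list(train = subset_fm(train_idx), test = subset_fm(test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' Confusion counts for binary -1/+1 labels
#'
#' Positive class (+1) is ictal, negative (-1) is healthy.
#'
#' @param y_true,y_pred Label vectors of equal length with values in
#'   \{-1, +1\}.
#' @return Object of class `"confusion_counts"` with fields `tp`, `tn`,
#'   `fp`, `fn` and the class totals `P = tp + fn`, `N = tn + fp`.
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- as.double(y_true); y_pred <- as.double(y_pred)
  if (length(y_true) != length(y_pred))
    stop("'y_true' and 'y_pred' must have equal length", call. = FALSE)
  if (!all(c(y_true, y_pred) %in% c(-1, 1)))
    stop("labels must be -1 or +1", call. = FALSE)
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == -1 & y_pred == -1)
  fp <- sum(y_true == -1 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == -1)
  confusion_counts(tp, tn, fp, fn)
}

#' @rdname confusion
#' @param tp,tn,fp,fn Non-negative counts (alternative direct constructor).
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 P = tp + fn, N = tn + fp),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts: TP %d  FN %d  |  TN %d  FP %d  (P = %d, N = %d)\n",
              x$tp, x$fn, x$tn, x$fp, x$P, x$N))
  invisible(x)
}

#' Accuracy, sensitivity and specificity
#'
#' Computes the three standard percentages from confusion counts:
#' accuracy \eqn{= 100 (TP + TN)/(P + N)}, sensitivity \eqn{= 100\,TP/P}
#' (true-positive rate over the ictal class), specificity
#' \eqn{= 100\,TN/N} (true-negative rate over the healthy class).
#'
#' @param counts A [confusion_counts()] object.
#' @param config Optional list snapshot of the run configuration, carried
#'   into the report.
#' @return Object of class `"metrics_report"` with the three percentages
#'   and the counts.
#' @export
classification_metrics <- function(counts, config = NULL) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$P == 0 || counts$N == 0)
    stop("metrics undefined: both P and N must be positive", call. = FALSE)
  structure(list(accuracy = 100 * (counts$tp + counts$tn) /
                   (counts$P + counts$N),
                 sensitivity = 100 * counts$tp / counts$P,
                 specificity = 100 * counts$tn / counts$N,
                 counts = counts, config = config),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Accuracy    : %6.2f %%\n", x$accuracy))
  cat(sprintf("Sensitivity : %6.2f %%\n", x$sensitivity))
  cat(sprintf("Specificity : %6.2f %%\n", x$specificity))
  print(x$counts)
  invisible(x)
}

# Recursively drop S3 classes so arbitrary config snapshots serialize.
strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else unclass(x)
}

#' Write a metrics report as JSON or a one-row CSV
#'
#' The CSV layout (one row: criterion settings, then the three
#' percentages) is convenient for aggregating runs across criterion
#' variants.
#'
#' @param report A [classification_metrics()] report.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  jsonlite::write_json(
    list(accuracy = report$accuracy, sensitivity = report$sensitivity,
         specificity = report$specificity,
         counts = report$counts[c("tp", "tn", "fp", "fn")],
         config = strip_classes(report$config)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_metrics_json
#' @export
write_metrics_csv <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  cfg <- report$config
  df <- data.frame(
    criterion = if (is.null(cfg$criterion)) NA_character_ else
      paste(cfg$criterion$base_statistic, cfg$criterion$direction),
    accuracy = sprintf("%.2f", report$accuracy),
    sensitivity = sprintf("%.2f", report$sensitivity),
    specificity = sprintf("%.2f", report$specificity))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
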