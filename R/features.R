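SUPPORTED_STATISTICS <- c("min", "max", "mean", "median", "mode",
                          "q1", "q3", "iqr", "range", "std")

#' Feature specification: which statistics to compute per subsample
#'
#' The default set is the nine descriptive statistics used throughout the
#' package: minimum, maximum, mean, median, mode, first and third quartile,
#' inter-quartile range and (sample) standard deviation.  A variant with
#' `range` in place of `iqr` can be requested by passing the names
#' explicitly.
#'
#' Conventions: quartiles use linear interpolation between order statistics
#' (the "type 7" rule); the mode is the most frequent value after rounding
#' to the nearest integer, ties broken toward the smallest value; the
#' standard deviation uses divisor \eqn{n - 1} and is defined as 0 for a
#' single observation.
#'
#' @param statistic_names Character vector of statistic names drawn from
#'   `min, max, mean, median, mode, q1, q3, iqr, range, std`.
#' @return An object of class `"feature_spec"`.
#' @export
feature_spec <- function(statistic_names = c("min", "max", "mean", "median",
                                             "mode", "q1", "q3", "iqr",
                                             "std")) {
  statistic_names <- as.character(statistic_names)
  bad <- setdiff(statistic_names, SUPPORTED_STATISTICS)
  if (length(bad))
    stop("unsupported statistics: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(statistic_names))
    stop("statistic names must be unique", call. = FALSE)
  if (!length(statistic_names))
    stop("at least one statistic is required", call. = FALSE)
  structure(list(statistic_names = statistic_names,
                 quantile_method = "linear",  # type-7 interpolation
                 mode_rounding = TRUE),
            class = "feature_spec")
}

# Most frequent value after integer rounding; ties go to the smallest value.
integer_mode <- function(x) {
  xi <- as.integer(round(x))
  lo <- min(xi)
  counts <- tabulate(xi - lo + 1L)
  as.double(lo - 1L + which.max(counts))
}

#' Descriptive statistics of one subsample
#'
#' Computes the statistics named in `spec`, in order, from one amplitude
#' sequence.  All statistics are invariant to permutation of the input.
#'
#' @param values Non-empty numeric vector.
#' @param spec A [feature_spec()].
#' @return Named numeric vector, one entry per statistic.
#' @examples
#' compute_statistics(c(1, 2, 2, 3, 10))
#' @export
compute_statistics <- function(values, spec = feature_spec()) {
  if (!length(values)) stop("'values' must be non-empty", call. = FALSE)
  if (anyNA(values)) stop("'values' must not contain NA", call. = FALSE)
  values <- as.double(values)
  names_ <- spec$statistic_names
  need_q <- any(names_ %in% c("q1", "q3", "iqr", "median"))
  if (need_q) {
    q <- stats::quantile(values, probs = c(0.25, 0.5, 0.75), type = 7,
                         names = FALSE)
  }
  out <- vapply(names_, function(s) {
    switch(s,
           min    = min(values),
           max    = max(values),
           mean   = mean(values),
           median = q[2L],
           mode   = integer_mode(values),
           q1     = q[1L],
           q3     = q[3L],
           iqr    = q[3L] - q[1L],
           range  = max(values) - min(values),
           std    = if (length(values) > 1L) stats::sd(values) else 0)
  }, numeric(1))
  names(out) <- names_
  out
}

#' Construct a feature matrix object
#'
#' A feature matrix holds one row per (record, sample) instance: the
#' concatenated subsample statistics, a class label (healthy = -1,
#' ictal = +1) and row provenance (class, record, sample).
#'
#' @param x Numeric matrix with column names `s<subsample>_<statistic>`.
#' @param label Numeric vector of -1/+1 labels, one per row.
#' @param provenance Data frame with columns `class`, `record`, `sample`.
#' @return An object of class `"feature_matrix"`.
#' @export
feature_matrix <- function(x, label, provenance) {
  x <- as.matrix(x)
  if (nrow(x) != length(label) || nrow(x) != nrow(provenance))
    stop("rows, labels and provenance must align", call. = FALSE)
  if (!all(label %in% c(-1, 1)))
    stop("labels must be -1 (healthy) or +1 (ictal)", call. = FALSE)
  structure(list(x = x, label = as.double(label),
                 provenance = as.data.frame(provenance)),
            class = "feature_matrix")
}

#' @export
dim.feature_matrix <- function(x) dim(x$x)

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d instances x %d features (%d healthy, %d ictal)\n",
              nrow(x$x), ncol(x$x), sum(x$label == -1), sum(x$label == 1)))
  cat("  columns:", paste(utils::head(colnames(x$x), 5), collapse = ", "),
      if (ncol(x$x) > 5) "..." else "", "\n")
  invisible(x)
}

#' @export
as.data.frame.feature_matrix <- function(x, ...) {
  cbind(x$provenance, label = x$label, as.data.frame(x$x))
}

#' Build the instance-by-feature matrix from a dataset
#'
#' For every record, `design$samples_per_record` simple random samples are
#' drawn; from each sample, `design$subsamples_per_sample` subsamples; each
#' subsample is reduced to the statistics in `spec`.  A row is one
#' (record, sample) instance, columns are subsample-major:
#' `s1_min, s1_max, ..., s2_min, ...`.
#'
#' With the Bonn-shaped defaults (2 classes x 100 records, 10 samples,
#' 5 subsamples, 9 statistics) the result is 2000 x 45.
#'
#' Randomness is reproducible: every (class, record, sample) triple gets a
#' deterministic substream of the master `seed`.
#'
#' @param dataset List of [eeg_record()] objects.
#' @param design A [sampling_design()].
#' @param spec A [feature_spec()].
#' @param seed Master seed.
#' @return A [feature_matrix()].
#' @export
build_feature_matrix <- function(dataset, design = sampling_design(),
                                 spec = feature_spec(), seed = 1L) {
  stopifnot(inherits(design, "sampling_design"),
            inherits(spec, "feature_spec"))
  too_short <- vapply(dataset, function(r)
    length(r$amplitudes) < design$population_size, logical(1))
  if (any(too_short))
    stop("record(s) shorter than the design population size: ",
         paste(vapply(dataset[too_short], function(r) r$record_id, ""),
               collapse = ", "), call. = FALSE)
  ns <- length(spec$statistic_names)
  k <- design$subsamples_per_sample
  n_rows <- length(dataset) * design$samples_per_record
  out <- matrix(NA_real_, n_rows, k * ns)
  colnames(out) <- paste0("s", rep(seq_len(k), each = ns), "_",
                          rep(spec$statistic_names, k))
  label <- numeric(n_rows)
  prov <- data.frame(class = character(n_rows), record = integer(n_rows),
                     sample = integer(n_rows))
  class_ids <- c(healthy = 1L, ictal = 2L)
  counter <- c(healthy = 0L, ictal = 0L)
  i <- 0L
  for (rec in dataset) {
    cl <- rec$class_label
    counter[cl] <- counter[cl] + 1L
    r <- counter[[cl]]
    amp <- as.double(rec$amplitudes[seq_len(design$population_size)])
    for (s in seq_len(design$samples_per_record)) {
      subs <- with_local_seed(substream_seed(seed, class_ids[[cl]], r, s), {
        samp <- draw_sample(design$population_size, design$sample_size)
        draw_subsamples(samp, design$subsample_size, k)
      })
      i <- i + 1L
      out[i, ] <- unlist(lapply(subs, function(ix)
        compute_statistics(amp[ix], spec)), use.names = FALSE)
      label[i] <- if (cl == "ictal") 1 else -1
      prov$class[i] <- cl; prov$record[i] <- r; prov$sample[i] <- s
    }
  }
  feature_matrix(out, label, prov)
}

#' Write / read a feature matrix as CSV
#'
#' The CSV holds the provenance columns, the label column and the feature
#' columns, with values formatted to 10 significant digits so that files
#' are byte-stable across runs.
#'
#' @param fm A [feature_matrix()].
#' @param path Output (input) path.
#' @return `path` invisibly; `read_feature_csv` returns a
#'   [feature_matrix()].
#' @export
write_feature_csv <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- as.data.frame(fm)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.10g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- c("class", "record", "sample", "label")
  if (!all(meta %in% names(df)))
    stop("not a feature-matrix CSV (missing metadata columns)",
         call. = FALSE)
  feature_matrix(as.matrix(df[setdiff(names(df), meta)]), df$label,
                 df[c("class", "record", "sample")])
}
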