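SFS_STATISTICS <- c("mean", "max", "min", "mode", "median", "std")

# One scalar statistic of a numeric vector, by name.
scalar_statistic <- function(name, v) {
  switch(name,
         mean   = mean(v),
         max    = max(v),
         min    = min(v),
         mode   = integer_mode(v),
         median = stats::median(v),
         std    = if (length(v) > 1L) stats::sd(v) else 0,
         stop("unknown statistic: ", name, call. = FALSE))
}

#' Threshold criterion for sequential feature selection
#'
#' The selection rule reduces every feature column to one scalar summary
#' \eqn{r_j} (default: the column mean), computes the criterion value
#' \eqn{\delta} as a base statistic of the summaries
#' \eqn{\{r_1, \dots, r_n\}}, and keeps column \eqn{j} when
#' \eqn{\delta \ge r_j} (direction `"ge"`) or \eqn{\delta \le r_j}
#' (direction `"le"`).  The configured direction is non-strict; the strict
#' complements `"lt"` and `"gt"` are accepted so that the two directions
#' partition the columns exactly.
#'
#' @param base_statistic Statistic applied to the column summaries to give
#'   the threshold: one of `mean, max, min, mode, median, std`.
#' @param direction `"ge"`, `"le"`, or a strict complement `"gt"`/`"lt"`.
#' @param column_summary Statistic reducing each column to a scalar
#'   (default `"mean"`).
#' @return An object of class `"sfs_criterion"`.
#' @export
sfs_criterion <- function(base_statistic = "mean",
                          direction = c("ge", "le", "gt", "lt"),
                          column_summary = "mean") {
  direction <- match.arg(direction)
  if (!base_statistic %in% SFS_STATISTICS)
    stop("'base_statistic' must be one of: ",
         paste(SFS_STATISTICS, collapse = ", "), call. = FALSE)
  if (!column_summary %in% SFS_STATISTICS)
    stop("'column_summary' must be one of: ",
         paste(SFS_STATISTICS, collapse = ", "), call. = FALSE)
  structure(list(base_statistic = base_statistic, direction = direction,
                 column_summary = column_summary),
            class = "sfs_criterion")
}

#' Criterion value and per-column summaries
#'
#' @param fm A [feature_matrix()] (or bare numeric matrix).
#' @param criterion An [sfs_criterion()].
#' @return List with `delta` (the threshold) and `column_summaries`
#'   (named vector \eqn{r_j}).
#' @export
compute_criterion <- function(fm, criterion = sfs_criterion()) {
  x <- if (inherits(fm, "feature_matrix")) fm$x else as.matrix(fm)
  if (!nrow(x) || !ncol(x))
    stop("feature matrix must be non-empty", call. = FALSE)
  r <- apply(x, 2L, function(col) scalar_statistic(criterion$column_summary,
                                                   col))
  list(delta = scalar_statistic(criterion$base_statistic, r),
       column_summaries = r)
}

#' Select feature columns by the threshold criterion
#'
#' Starting from an empty selected set, columns are scanned in ascending
#' index order and column \eqn{j} is added when its summary \eqn{r_j}
#' satisfies the criterion (see [sfs_criterion()]).  If no column
#' qualifies, the result is flagged degenerate and all columns are
#' retained so the pipeline can proceed.
#'
#' @param fm A [feature_matrix()] (or numeric matrix).
#' @param criterion An [sfs_criterion()].
#' @param delta Optional frozen threshold; when supplied it overrides the
#'   recomputed one (used when re-applying a previous selection).
#' @return An object of class `"sfs_result"` with fields `delta`,
#'   `column_summaries`, `selected` (ascending indices), `n_features`,
#'   `degenerate` and the criterion.
#' @export
select_features <- function(fm, criterion = sfs_criterion(), delta = NULL) {
  cc <- compute_criterion(fm, criterion)
  if (is.null(delta)) delta <- cc$delta
  r <- cc$column_summaries
  keep <- switch(criterion$direction,
                 ge = delta >= r,
                 le = delta <= r,
                 gt = delta > r,
                 lt = delta < r)
  selected <- unname(which(keep))
  degenerate <- length(selected) == 0L
  if (degenerate) {
    warning("no column satisfies the criterion; retaining all columns",
            call. = FALSE)
    selected <- seq_along(r)
  }
  structure(list(delta = delta, column_summaries = r,
                 selected = selected, n_features = length(r),
                 degenerate = degenerate, criterion = criterion,
                 column_names = names(r)),
            class = "sfs_result")
}

#' @export
print.sfs_result <- function(x, ...) {
  cat(sprintf("SFS selection: %d of %d columns (criterion %s %s column %s, delta = %.6g)%s\n",
              length(x$selected), x$n_features,
              x$criterion$base_statistic,
              c(ge = ">=", le = "<=", gt = ">", lt = "<")[x$criterion$direction],
              x$criterion$column_summary, x$delta,
              if (x$degenerate) " [degenerate: nothing qualified]" else ""))
  invisible(x)
}

#' Project a feature matrix onto selected columns
#'
#' Restricts the matrix to the columns in `result$selected`; labels and
#' provenance are preserved.  A degenerate selection returns the matrix
#' unchanged.
#'
#' @param fm A [feature_matrix()].
#' @param result An [sfs_result()] (or integer vector of column indices).
#' @return A [feature_matrix()] with the selected columns.
#' @export
project <- function(fm, result) {
  stopifnot(inherits(fm, "feature_matrix"))
  idx <- if (inherits(result, "sfs_result")) result$selected
         else as.integer(result)
  if (any(idx < 1L | idx > ncol(fm$x)))
    stop("selected column index out of range", call. = FALSE)
  feature_matrix(fm$x[, idx, drop = FALSE], fm$label, fm$provenance)
}

#' Serialize an SFS result to JSON
#'
#' @param result An [sfs_result()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sfs_json <- function(result, path) {
  stopifnot(inherits(result, "sfs_result"))
  jsonlite::write_json(
    list(delta = result$delta,
         base_statistic = result$criterion$base_statistic,
         direction = result$criterion$direction,
         column_summary = result$criterion$column_summary,
         degenerate = result$degenerate,
         selected_columns = result$selected,
         column_names = result$column_names[result$selected]),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
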