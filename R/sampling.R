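#' Cochran sample size with finite-population correction
#'
#' Computes the simple-random-sampling sample size for estimating a
#' proportion: the uncorrected size \eqn{ss_0 = z^2 p (1-p) / c^2} is shrunk
#' by the finite-population correction \eqn{ss_0 / (1 + (ss_0 - 1)/N)} and
#' rounded half-up to an integer.  Applied hierarchically, the formula gives
#' the per-record sample size (population = observations in one record) and
#' then the subsample size (population = the sample size).
#'
#' @param population Number of observations in the population (\eqn{N \ge 1}).
#' @param z_score Standard-normal multiplier for the confidence level
#'   (2.58 for 99\%).
#' @param proportion Assumed population proportion, in (0, 1); 0.5 is the
#'   conservative maximum-variance choice.
#' @param margin Confidence-interval half-width as a fraction (> 0).
#' @return Integer sample size in `[1, population]`.
#' @examples
#' cochran_sample_size(4097, 2.58, 0.5, 0.01)  # 3288
#' cochran_sample_size(3288, 2.58, 0.5, 0.01)  # 2746
#' @export
cochran_sample_size <- function(population, z_score = 2.58, proportion = 0.5,
                                margin = 0.01) {
  if (!is.numeric(population) || length(population) != 1L || population < 1)
    stop("'population' must be a single value >= 1", call. = FALSE)
  if (!is.numeric(margin) || length(margin) != 1L || margin <= 0)
    stop("'margin' must be a single positive value", call. = FALSE)
  if (!is.numeric(proportion) || proportion <= 0 || proportion >= 1)
    stop("'proportion' must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(z_score) || z_score <= 0)
    stop("'z_score' must be positive", call. = FALSE)
  ss0 <- z_score^2 * proportion * (1 - proportion) / margin^2
  ss <- ss0 / (1 + (ss0 - 1) / population)
  n <- as.integer(floor(ss + 0.5))  # round half-up, not banker's rounding
  max(1L, min(n, as.integer(population)))
}

#' Simple-random-sampling design for one EEG record
#'
#' Bundles the population/sample/subsample sizes and the confidence
#' parameters that generate them.  When `sample_size` or `subsample_size`
#' is `NULL` it is derived with [cochran_sample_size()]: the sample size
#' from `population_size`, the subsample size from the sample size.
#'
#' The defaults reproduce the hierarchical design used throughout the
#' package for Bonn-layout records: 4097 observations per record, 10
#' samples of 3288 per record, 5 subsamples of 2746 per sample.
#'
#' @param population_size Observations per record.
#' @param z_score,proportion,margin Confidence parameters passed to
#'   [cochran_sample_size()].
#' @param samples_per_record Number of samples drawn from each record.
#' @param subsamples_per_sample Number of subsamples drawn from each sample.
#' @param sample_size,subsample_size Optional explicit sizes overriding the
#'   Cochran-derived ones.
#' @return An object of class `"sampling_design"`.
#' @examples
#' d <- sampling_design()
#' d$sample_size     # 3288
#' d$subsample_size  # 2746
#' @export
sampling_design <- function(population_size = 4097L, z_score = 2.58,
                            proportion = 0.5, margin = 0.01,
                            samples_per_record = 10L,
                            subsamples_per_sample = 5L,
                            sample_size = NULL, subsample_size = NULL) {
  if (samples_per_record < 1L || subsamples_per_sample < 1L)
    stop("sample and subsample counts must be >= 1", call. = FALSE)
  if (is.null(sample_size))
    sample_size <- cochran_sample_size(population_size, z_score, proportion,
                                       margin)
  if (is.null(subsample_size))
    subsample_size <- cochran_sample_size(sample_size, z_score, proportion,
                                          margin)
  if (!(subsample_size >= 1L && subsample_size <= sample_size &&
        sample_size <= population_size))
    stop("need 1 <= subsample_size <= sample_size <= population_size",
         call. = FALSE)
  structure(list(population_size = as.integer(population_size),
                 z_score = z_score, proportion = proportion, margin = margin,
                 sample_size = as.integer(sample_size),
                 subsample_size = as.integer(subsample_size),
                 samples_per_record = as.integer(samples_per_record),
                 subsamples_per_sample = as.integer(subsamples_per_sample)),
            class = "sampling_design")
}

#' @export
print.sampling_design <- function(x, ...) {
  cat("SRS sampling design\n")
  cat(sprintf("  population per record : %d\n", x$population_size))
  cat(sprintf("  samples per record    : %d of size %d\n",
              x$samples_per_record, x$sample_size))
  cat(sprintf("  subsamples per sample : %d of size %d\n",
              x$subsamples_per_sample, x$subsample_size))
  cat(sprintf("  confidence parameters : z = %g, p = %g, c = %g\n",
              x$z_score, x$proportion, x$margin))
  invisible(x)
}

# Deterministic substream seed from a master seed and a path of integer ids
# (class, record, sample, ...).  A small LCG-style fold keeps everything
# exact in doubles (< 2^53) and inside 32-bit integer range.
substream_seed <- function(master, ...) {
  s <- as.double(master) %% 2147483647
  for (k in c(...)) {
    s <- (s * 69069 + as.double(k) + 1) %% 2147483647
  }
  as.integer(s)
}

# Evaluate expr under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Draw one simple random sample of observation indices
#'
#' Draws `size` distinct indices uniformly without replacement from
#' `1:n` and returns them in ascending order, so that the sampled values
#' keep their temporal order.
#'
#' @param n Record length (population size).
#' @param size Sample size, `<= n`.
#' @param seed Optional integer seed for a reproducible draw; the caller's
#'   RNG state is left untouched.
#' @return Sorted integer vector of `size` distinct indices in `1:n`.
#' @export
draw_sample <- function(n, size, seed = NULL) {
  n <- as.integer(n); size <- as.integer(size)
  if (size < 1L || size > n)
    stop("sample size must lie in [1, record length]", call. = FALSE)
  sort(with_local_seed(seed, sample.int(n, size)))
}

#' Draw subsamples from a parent sample
#'
#' Draws `k` independent subsamples of `size` distinct positions each from
#' the parent sample `idx` (without replacement within a subsample; overlap
#' across subsamples is permitted).  Each subsample keeps ascending order.
#'
#' @param idx Integer vector: the parent sample's observation indices.
#' @param size Subsample size, `<= length(idx)`.
#' @param k Number of subsamples (>= 1).
#' @param seed Optional integer seed (see [draw_sample()]).
#' @return List of `k` sorted integer vectors of length `size`.
#' @export
draw_subsamples <- function(idx, size, k, seed = NULL) {
  size <- as.integer(size); k <- as.integer(k)
  if (size < 1L || size > length(idx))
    stop("subsample size must lie in [1, sample length]", call. = FALSE)
  if (k < 1L) stop("'k' must be >= 1", call. = FALSE)
  with_local_seed(seed, {
    lapply(seq_len(k), function(j) sort(idx[sample.int(length(idx), size)]))
  })
}
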