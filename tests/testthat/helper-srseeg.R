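# Small study conditions shared across tests: 600-point records, a
# proportionally scaled sampling design.
tiny_config <- function(records_per_class = 4L, record_length = 600L,
                        seed = 42L, ...) {
  synthetic_config(records_per_class = records_per_class,
                   record_length = record_length, seed = seed, ...)
}

tiny_design <- function(population = 600L, samples = 3L, subsamples = 2L) {
  sampling_design(population, samples_per_record = samples,
                  subsamples_per_sample = subsamples)
}

# Feature matrix with arbitrary contents, for selection/split tests.
fake_feature_matrix <- function(x, label = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("c", seq_len(ncol(x)))
  if (is.null(label)) label <- rep_len(c(-1, 1), nrow(x))
  feature_matrix(x, label,
                 data.frame(class = ifelse(label > 0, "ictal", "healthy"),
                            record = seq_len(nrow(x)), sample = 1L))
}

# Independent dense-solve oracle for the LS-SVM dual system, written with
# explicit loops and qr.solve so it shares no code with the implementation.
lssvm_oracle <- function(X, y, gamma, sigma2) {
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      K[i, j] <- exp(-sum((X[i, ] - X[j, ])^2) / sigma2)
    }
  }
  Omega <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) Omega[i, j] <- y[i] * y[j] * K[i, j]
  }
  A <- rbind(c(0, y), cbind(y, Omega + diag(n) / gamma))
  sol <- qr.solve(A, c(0, rep(1, n)))
  list(bias = sol[1], alphas = sol[-1])
}
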