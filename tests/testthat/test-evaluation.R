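test_that("stratified split preserves class proportions and partitions rows", {
  set.seed(31)
  fm <- fake_feature_matrix(matrix(rnorm(2000 * 3), 2000),
                            label = rep(c(-1, 1), each = 1000))
  sp <- stratified_split(fm, 0.5, seed = 5)
  expect_identical(nrow(sp$train$x), 1000L)
  expect_identical(nrow(sp$test$x), 1000L)
  expect_identical(sum(sp$train$label == 1), 500L)
  expect_identical(sum(sp$train$label == -1), 500L)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  expect_identical(sort(c(sp$train_idx, sp$test_idx)), 1:2000)
  # determinism
  sp2 <- stratified_split(fm, 0.5, seed = 5)
  expect_identical(sp$train_idx, sp2$train_idx)
  # minimal stratification: 4 rows, 2 per class
  mini <- fake_feature_matrix(matrix(rnorm(8), 4), label = c(-1, -1, 1, 1))
  spm <- stratified_split(mini, 0.5, seed = 1)
  expect_identical(sum(spm$train$label == 1), 1L)
  expect_identical(sum(spm$train$label == -1), 1L)
  expect_error(stratified_split(fm, 1), "train_fraction")
  solo <- fake_feature_matrix(matrix(rnorm(6), 3), label = c(-1, -1, 1))
  expect_error(stratified_split(solo, 0.5), "at least 2 rows")
})

test_that("confusion counts tally the four cells", {
  cc <- confusion(c(1, -1), c(1, -1))
  expect_identical(c(cc$tp, cc$tn, cc$fp, cc$fn), c(1L, 1L, 0L, 0L))
  cc2 <- confusion(c(1, 1, 1, 1, 1, -1, -1, -1),
                   c(1, 1, 1, -1, -1, -1, -1, 1))
  expect_identical(c(cc2$tp, cc2$fn, cc2$tn, cc2$fp), c(3L, 2L, 2L, 1L))
  expect_identical(cc2$P, 5L)
  expect_identical(cc2$N, 3L)
  # degenerate predictor: everything +1
  cc3 <- confusion(c(1, -1, -1), c(1, 1, 1))
  expect_identical(cc3$fp, cc3$N)
  expect_identical(cc3$fn, 0L)
  expect_error(confusion(c(1, -1), c(1)), "equal length")
  expect_error(confusion(c(1, 0), c(1, 1)), "-1 or \\+1")
})

test_that("accuracy, sensitivity, specificity follow their definitions", {
  perfect <- classification_metrics(confusion_counts(7, 9, 0, 0))
  expect_equal(c(perfect$accuracy, perfect$sensitivity,
                 perfect$specificity), c(100, 100, 100))
  m <- classification_metrics(confusion_counts(3, 2, 1, 2))
  expect_equal(m$accuracy, 62.5)
  expect_equal(m$sensitivity, 60)
  expect_equal(m$specificity, 66.67, tolerance = 1e-4)
  # a near-perfect 1000-instance split
  m2 <- classification_metrics(confusion_counts(499, 500, 0, 1))
  expect_equal(c(m2$accuracy, m2$sensitivity, m2$specificity),
               c(99.9, 99.8, 100))
  expect_error(classification_metrics(confusion_counts(0, 5, 2, 0)),
               "undefined")
  expect_error(confusion_counts(-1, 0, 0, 0), "non-negative")
})

test_that("accuracy decomposes exactly into class-weighted rates", {
  set.seed(32)
  for (i in 1:1000) {
    tp <- sample(0:50, 1); fn <- sample(0:50, 1)
    tn <- sample(0:50, 1); fp <- sample(0:50, 1)
    if (tp + fn == 0 || tn + fp == 0) next
    m <- classification_metrics(confusion_counts(tp, tn, fp, fn))
    expect_equal(m$accuracy * (m$counts$P + m$counts$N),
                 m$sensitivity * m$counts$P + m$specificity * m$counts$N,
                 tolerance = 1e-9)
  }
})

test_that("metrics are invariant to joint permutation of the labels", {
  set.seed(33)
  y <- sample(c(-1, 1), 60, replace = TRUE)
  y[1:2] <- c(-1, 1)
  p <- sample(c(-1, 1), 60, replace = TRUE)
  m1 <- classification_metrics(confusion(y, p))
  ord <- sample(60)
  m2 <- classification_metrics(confusion(y[ord], p[ord]))
  expect_equal(m1$accuracy, m2$accuracy)
  expect_equal(m1$sensitivity, m2$sensitivity)
  expect_equal(m1$specificity, m2$specificity)
})

test_that("metrics reports serialize to JSON and one-row CSV", {
  rep_ <- classification_metrics(confusion_counts(3, 2, 1, 2),
                                 config = list(criterion = sfs_criterion()))
  pj <- tempfile(fileext = ".json"); pc <- tempfile(fileext = ".csv")
  write_metrics_json(rep_, pj)
  back <- jsonlite::read_json(pj, simplifyVector = TRUE)
  expect_equal(back$accuracy, 62.5)
  write_metrics_csv(rep_, pc)
  csv <- utils::read.csv(pc)
  expect_equal(csv$accuracy, 62.5)
  expect_identical(csv$criterion, "mean ge")
  unlink(c(pj, pc))
})
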