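test_that("RBF kernel evaluates the Gaussian of squared distance", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), 1), 1)
  expect_equal(rbf_kernel(0, 1, 1), exp(-1))        # ||x-y||^2 == sigma2
  expect_equal(rbf_kernel(0, 2, 1), exp(-4))
  expect_equal(rbf_kernel(0, 2, 1, scale = "half"), exp(-2))
  expect_error(rbf_kernel(c(1, 2), 1, 1), "dimension")
  expect_error(rbf_kernel(0, 1, 0), "positive")
})

test_that("kernel matrix is symmetric with a unit diagonal", {
  set.seed(21)
  X <- matrix(rnorm(30), 10)
  K <- srseeg:::rbf_kernel_matrix(X, X, 2)
  expect_equal(K, t(K))
  expect_equal(diag(K), rep(1, 10))
  expect_true(all(K > 0 & K <= 1))
})

test_that("mirror-symmetric two-point problem has zero bias", {
  X <- matrix(c(-1, 1), ncol = 1)
  m <- lssvm(X, c(1, -1), gamma = 3, sigma2 = 2)
  expect_equal(m$bias, 0, tolerance = 1e-12)
  f <- predict(m, X, type = "decision")
  expect_true(f[1] > 0 && f[2] < 0)
  expect_equal(predict(m, X), c(1, -1))
  # the midpoint has decision value exactly 0 by symmetry -> +1 tie rule
  expect_equal(predict(m, matrix(0), type = "decision"), 0)
  expect_equal(predict(m, matrix(0)), 1)
})

test_that("dual solution matches an independent dense-solve oracle", {
  set.seed(22)
  for (trial in 1:50) {
    n <- sample(4:20, 1)
    p <- sample(1:5, 1)
    X <- matrix(rnorm(n * p), n)
    y <- c(-1, 1, sample(c(-1, 1), n - 2, replace = TRUE))
    gamma <- runif(1, 0.5, 50)
    sigma2 <- runif(1, 0.3, 5)
    m <- lssvm(X, y, gamma = gamma, sigma2 = sigma2)
    o <- lssvm_oracle(X, y, gamma, sigma2)
    expect_lt(max(abs(c(m$bias - o$bias, m$alphas - o$alphas))), 1e-8)
  }
})

test_that("relabeling y -> -y flips all decision values", {
  set.seed(23)
  X <- matrix(rnorm(24), 12)
  y <- rep(c(-1, 1), 6)
  m1 <- lssvm(X, y)
  m2 <- lssvm(X, -y)
  Xnew <- matrix(rnorm(10), 5)
  expect_equal(predict(m1, Xnew, type = "decision"),
               -predict(m2, Xnew, type = "decision"), tolerance = 1e-8)
})

test_that("large gamma interpolates well-separated training data", {
  set.seed(24)
  X <- rbind(matrix(rnorm(20, mean = -3, sd = 0.3), ncol = 2),
             matrix(rnorm(20, mean = 3, sd = 0.3), ncol = 2))
  y <- rep(c(-1, 1), each = 10)
  m <- lssvm(X, y, gamma = 1e6, sigma2 = 1)
  expect_identical(predict(m, X), y)
  # a duplicate of a training row gets that row's label
  expect_identical(predict(m, X[3, , drop = FALSE]), y[3])
})

test_that("training input is validated", {
  X <- matrix(rnorm(10), 5)
  expect_error(lssvm(X, rep(1, 5)), "both classes")
  expect_error(lssvm(X, c(1, -1, 0, 1, -1)), "-1 or \\+1")
  expect_error(lssvm(X[1, , drop = FALSE], 1), "two training rows")
  expect_error(lssvm(X, c(1, -1, 1, -1, 1), gamma = 0), "positive")
  m <- lssvm(X, c(1, -1, 1, -1, 1))
  expect_error(predict(m, matrix(0, 1, 3)), "columns")
})

test_that("formula and factor interfaces map the second level to +1", {
  set.seed(25)
  df <- data.frame(a = c(rnorm(10, -2), rnorm(10, 2)),
                   b = rnorm(20),
                   cls = factor(rep(c("healthy", "ictal"), each = 10)))
  m <- lssvm(cls ~ a + b, df, gamma = 100)
  pred <- predict(m, df)
  expect_s3_class(pred, "factor")
  expect_identical(levels(pred), c("healthy", "ictal"))
  expect_gt(mean(pred == df$cls), 0.9)
})

test_that("standardization is learned on training data and reapplied", {
  set.seed(26)
  X <- cbind(rnorm(20, sd = 1000), rnorm(20, sd = 0.01))
  X[1:10, 1] <- X[1:10, 1] - 3000
  y <- rep(c(-1, 1), each = 10)
  m <- lssvm(X, y, standardize = TRUE)
  expect_identical(predict(m, X), y)
  expect_length(m$center, 2L)
})

test_that("model accessors expose coefficients, fit and slack", {
  set.seed(27)
  X <- matrix(rnorm(16), 8)
  y <- rep(c(-1, 1), 4)
  m <- lssvm(X, y, gamma = 5)
  cf <- coef(m)
  expect_length(cf, 9L)
  expect_equal(unname(cf["bias"]), m$bias)
  # LS-SVM identity: alpha_i = gamma * e_i with slack e_i = 1 - y_i f(x_i)
  expect_equal(m$alphas, 5 * y * residuals(m), tolerance = 1e-8)
  expect_equal(fitted(m), predict(m, X, type = "decision"),
               tolerance = 1e-10)
  expect_output(print(summary(m)), "training accuracy")
})
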