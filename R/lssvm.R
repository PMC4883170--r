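#' Radial-basis-function kernel
#'
#' Computes \eqn{K(x, y) = \exp(-\|x - y\|^2 / \sigma^2)} (the LS-SVMlab
#' scaling).  The variant \eqn{\exp(-\|x-y\|^2 / 2\sigma^2)} is available
#' with `scale = "half"`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param sigma2 Kernel width \eqn{\sigma^2 > 0}.
#' @param scale `"sigma2"` (default) or `"half"`.
#' @return Similarity in (0, 1].
#' @examples
#' rbf_kernel(0, 2, 1)  # exp(-4)
#' @export
rbf_kernel <- function(x, y, sigma2 = 1, scale = c("sigma2", "half")) {
  scale <- match.arg(scale)
  if (length(x) != length(y))
    stop("'x' and 'y' must have the same dimension", call. = FALSE)
  if (sigma2 <= 0) stop("'sigma2' must be positive", call. = FALSE)
  d2 <- sum((x - y)^2)
  exp(-d2 / if (scale == "half") 2 * sigma2 else sigma2)
}

# Pairwise kernel matrix between the rows of X and Y.
rbf_kernel_matrix <- function(X, Y, sigma2, scale = "sigma2") {
  sx <- rowSums(X^2)
  sy <- rowSums(Y^2)
  d2 <- outer(sx, sy, "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0  # numerical noise from the expansion
  exp(-d2 / if (scale == "half") 2 * sigma2 else sigma2)
}

#' Least-squares support vector machine
#'
#' Fits a binary LS-SVM classifier with an RBF kernel.  Training reduces
#' to one dense linear system (no quadratic programming): with
#' \eqn{\Omega_{ij} = y_i y_j K(x_i, x_j)}, solve
#' \deqn{\begin{pmatrix} 0 & y^\top \\ y & \Omega + I/\gamma \end{pmatrix}
#'   \begin{pmatrix} b \\ \alpha \end{pmatrix} =
#'   \begin{pmatrix} 0 \\ 1 \end{pmatrix}}
#' and classify with \eqn{f(x) = \sum_i \alpha_i y_i K(x, x_i) + b}.
#' The solve is validated by a relative-residual check; an ill-conditioned
#' system gets one round of diagonal jitter (`1e-10 * trace/n`) before
#' failing.
#'
#' Defaults \eqn{\gamma = 10}, \eqn{\sigma^2 = 1}.  Features are used raw
#' by default; `standardize = TRUE` z-scores columns with the training
#' means and standard deviations (applied identically at prediction time).
#'
#' @param x Numeric matrix of training rows, or a [feature_matrix()], or a
#'   formula (with `data`).
#' @param y Labels in \{-1, +1\} (or a two-level factor; the second level
#'   maps to +1).  Ignored when `x` is a feature matrix or formula.
#' @param gamma Regularization \eqn{\gamma > 0}.
#' @param sigma2 RBF width \eqn{\sigma^2 > 0}.
#' @param standardize Z-score the feature columns before the kernel.
#' @param kernel_scale `"sigma2"` (LS-SVMlab convention) or `"half"`.
#' @param ... Passed between methods.
#' @return An object of class `"lssvm"`: dual coefficients `alphas`, bias
#'   `bias`, the kernel parameters, and the stored training inputs.
#' @examples
#' X <- matrix(c(-1, 1), ncol = 1)
#' m <- lssvm(X, c(1, -1))
#' predict(m, X)
#' @export
lssvm <- function(x, ...) UseMethod("lssvm")

#' @rdname lssvm
#' @export
lssvm.default <- function(x, y, gamma = 10, sigma2 = 1,
                          standardize = FALSE,
                          kernel_scale = c("sigma2", "half"), ...) {
  kernel_scale <- match.arg(kernel_scale)
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  ylevels <- NULL
  if (is.factor(y)) {
    if (nlevels(y) != 2L)
      stop("factor response must have exactly two levels", call. = FALSE)
    ylevels <- levels(y)
    y <- ifelse(as.integer(y) == 2L, 1, -1)
  }
  y <- as.double(y)
  if (nrow(X) != length(y))
    stop("'x' rows and 'y' length must match", call. = FALSE)
  if (nrow(X) < 2L) stop("need at least two training rows", call. = FALSE)
  if (!all(y %in% c(-1, 1)))
    stop("labels must be -1 or +1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("both classes must be present in the training data",
         call. = FALSE)
  if (gamma <= 0 || sigma2 <= 0)
    stop("'gamma' and 'sigma2' must be positive", call. = FALSE)

  center <- scale_ <- NULL
  if (standardize) {
    center <- colMeans(X)
    scale_ <- apply(X, 2L, stats::sd)
    scale_[scale_ == 0] <- 1
    X <- sweep(sweep(X, 2L, center), 2L, scale_, "/")
  }

  n <- nrow(X)
  K <- rbf_kernel_matrix(X, X, sigma2, kernel_scale)
  Omega <- (y %o% y) * K
  A <- matrix(0, n + 1L, n + 1L)
  A[1L, -1L] <- y
  A[-1L, 1L] <- y
  A[-1L, -1L] <- Omega + diag(1 / gamma, n)
  rhs <- c(0, rep(1, n))

  solve_checked <- function(A) {
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(sol)) return(NULL)
    resid <- max(abs(A %*% sol - rhs)) / max(1, max(abs(rhs)))
    if (resid > 1e-8) NULL else sol
  }
  sol <- solve_checked(A)
  if (is.null(sol)) {
    jitter <- 1e-10 * sum(diag(A)[-1L]) / n
    A[cbind(2:(n + 1L), 2:(n + 1L))] <- diag(A)[-1L] + jitter
    sol <- solve_checked(A)
    if (is.null(sol))
      stop("LS-SVM system is singular or ill-conditioned even after jitter",
           call. = FALSE)
  }

  model <- structure(list(alphas = sol[-1L], bias = sol[1L],
                          gamma = gamma, sigma2 = sigma2,
                          kernel_scale = kernel_scale,
                          train_inputs = X, train_labels = y,
                          center = center, scale = scale_,
                          ylevels = ylevels,
                          call = match.call(expand.dots = FALSE)),
                     class = "lssvm")
  model$decision <- as.vector(K %*% (model$alphas * y) + model$bias)
  model
}

#' @rdname lssvm
#' @export
lssvm.feature_matrix <- function(x, ...) {
  lssvm.default(x$x, x$label, ...)
}

#' @rdname lssvm
#' @param data Data frame for the formula interface.
#' @export
lssvm.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  m <- lssvm.default(X, y, ...)
  m$terms <- attr(mf, "terms")
  m$call <- match.call(expand.dots = FALSE)
  m
}

#' Predict method for LS-SVM fits
#'
#' @param object An [lssvm()] fit.
#' @param newdata Matrix (or data frame for formula fits, or
#'   [feature_matrix()]) of rows to classify.  Defaults to the training
#'   inputs.
#' @param type `"class"` for -1/+1 labels (a decision value of exactly 0
#'   maps to +1), `"decision"` for the raw decision values \eqn{f(x)}.
#' @param ... Unused.
#' @return Numeric vector of labels or decision values (a factor when the
#'   model was trained on a factor response and `type = "class"`).
#' @export
predict.lssvm <- function(object, newdata = NULL,
                          type = c("class", "decision"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    f <- object$decision
  } else {
    if (inherits(newdata, "feature_matrix")) newdata <- newdata$x
    if (!is.null(object$terms)) {
      mf <- stats::model.frame(stats::delete.response(object$terms),
                               as.data.frame(newdata))
      newdata <- stats::model.matrix(stats::delete.response(object$terms),
                                     mf)
      newdata <- newdata[, colnames(newdata) != "(Intercept)", drop = FALSE]
    }
    X <- as.matrix(newdata)
    storage.mode(X) <- "double"
    if (ncol(X) != ncol(object$train_inputs))
      stop("newdata has ", ncol(X), " columns; model was trained on ",
           ncol(object$train_inputs), call. = FALSE)
    if (!is.null(object$center))
      X <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
    K <- rbf_kernel_matrix(X, object$train_inputs, object$sigma2,
                           object$kernel_scale)
    f <- as.vector(K %*% (object$alphas * object$train_labels) +
                     object$bias)
  }
  if (type == "decision") return(f)
  lab <- ifelse(f >= 0, 1, -1)
  if (!is.null(object$ylevels))
    lab <- factor(object$ylevels[(lab + 3) / 2], levels = object$ylevels)
  lab
}

#' @export
print.lssvm <- function(x, ...) {
  cat("Least-squares SVM (RBF kernel)\n")
  cat(sprintf("  %d training rows, %d features; gamma = %g, sigma2 = %g%s\n",
              nrow(x$train_inputs), ncol(x$train_inputs), x$gamma, x$sigma2,
              if (!is.null(x$center)) ", standardized features" else ""))
  cat(sprintf("  bias b = %.6g; |alpha| in [%.3g, %.3g]\n", x$bias,
              min(abs(x$alphas)), max(abs(x$alphas))))
  invisible(x)
}

#' @export
summary.lssvm <- function(object, ...) {
  pred <- ifelse(object$decision >= 0, 1, -1)
  acc <- mean(pred == object$train_labels) * 100
  out <- list(model = object, train_accuracy = acc,
              decision_range = range(object$decision))
  class(out) <- "summary.lssvm"
  out
}

#' @export
print.summary.lssvm <- function(x, ...) {
  print(x$model)
  cat(sprintf("  training accuracy: %.2f %%; decision values in [%.4g, %.4g]\n",
              x$train_accuracy, x$decision_range[1], x$decision_range[2]))
  invisible(x)
}

#' @export
coef.lssvm <- function(object, ...) {
  c(bias = object$bias, alpha = object$alphas)
}

#' @export
fitted.lssvm <- function(object, ...) object$decision

#' Residuals of an LS-SVM fit
#'
#' Returns the response residuals \eqn{y_i - f(x_i)} on the training rows.
#' These relate to the LS-SVM slack variables \eqn{e_i = 1 - y_i f(x_i)}
#' by \eqn{y_i - f(x_i) = y_i e_i}, so the dual identity
#' \eqn{\alpha_i = \gamma e_i} reads \eqn{\alpha_i = \gamma y_i (y_i - f(x_i))}.
#'
#' @param object An [lssvm()] fit.
#' @param ... Unused.
#' @export
residuals.lssvm <- function(object, ...) {
  object$train_labels - object$decision
}

#' @export
plot.lssvm <- function(x, ...) {
  f <- x$decision
  cls <- factor(ifelse(x$train_labels > 0, "ictal (+1)", "healthy (-1)"))
  graphics::stripchart(f ~ cls, vertical = TRUE, pch = 16, method = "jitter",
                       col = c("#2166AC", "#B2182B"),
                       ylab = "decision value f(x)",
                       main = "LS-SVM training decision values", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
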