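#' Gaussian (RBF) kernel between two feature vectors
#'
#' `k(x, xi) = exp(-||x - xi||^2 / (2 * sigma^2))` with the squared
#' Euclidean norm, so the result lies in `(0, 1]`.
#'
#' @param x,xi numeric vectors of equal length.
#' @param sigma kernel width, strictly positive.
#' @return Scalar kernel value.
#' @export
#' @examples
#' rbf_kernel(c(0), c(3), 1)   # exp(-4.5)
rbf_kernel <- function(x, xi, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("`sigma` must be a single positive number", call. = FALSE)
  }
  if (length(x) != length(xi)) {
    stop("`x` and `xi` must have the same length", call. = FALSE)
  }
  exp(-sum((x - xi)^2) / (2 * sigma^2))
}

#' RBF Gram matrix of a sample matrix
#'
#' Symmetric positive semi-definite kernel matrix with unit diagonal.
#'
#' @param X numeric matrix, one sample per row.
#' @param sigma kernel width.
#' @return `nrow(X) x nrow(X)` kernel matrix.
#' @export
kernel_matrix <- function(X, sigma) {
  X <- as.matrix(X)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("`sigma` must be a single positive number", call. = FALSE)
  }
  sq <- rowSums(X^2)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0  # numerical negative zeros
  exp(-d2 / (2 * sigma^2))
}

cross_kernel <- function(Xq, Xt, sigma) {
  Xq <- as.matrix(Xq); Xt <- as.matrix(Xt)
  d2 <- outer(rowSums(Xq^2), rowSums(Xt^2), `+`) - 2 * tcrossprod(Xq, Xt)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

#' Fit an LSSVM regression model
#'
#' Least-squares support vector machine: the equality-constrained squared
#' loss formulation whose Karush-Kuhn-Tucker conditions reduce training to
#' one dense `(l+1) x (l+1)` linear system
#'
#' \deqn{\begin{pmatrix} 0 & 1^T \\ 1 & K + g^{-1} I \end{pmatrix}
#'       \begin{pmatrix} b \\ \alpha \end{pmatrix} =
#'       \begin{pmatrix} 0 \\ y \end{pmatrix}}
#'
#' solved here with a dense LU factorization (partial pivoting).  The block
#' matrix is symmetric indefinite; a generic direct solve is robust at the
#' few-thousand-row scale this package targets and the first-row constraint
#' `sum(alpha) = 0` is verified post-hoc.
#'
#' @param X numeric training matrix, `l` rows of features.
#' @param y numeric response of length `l`.
#' @param g penalty (regularization) parameter, `> 0`; larger values fit
#'   the training data more tightly (inverse ridge strength).
#' @param sigma RBF kernel width, `> 0`.
#' @return Object of class `lssvm` with fields `train_inputs`, `alpha`
#'   (dual coefficients), `b` (bias), `g`, `sigma`.
#' @export
#' @examples
#' m <- lssvm_fit(matrix(1:5), c(1, 4, 9, 16, 25), g = 100, sigma = 2)
#' predict(m, matrix(3))
lssvm_fit <- function(X, y, g, sigma) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  l <- nrow(X)
  if (l < 1L || length(y) != l) {
    stop("`X` must have one row per element of `y`", call. = FALSE)
  }
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("training data must be finite", call. = FALSE)
  }
  if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || g <= 0) {
    stop("`g` must be a single positive number", call. = FALSE)
  }
  K <- kernel_matrix(X, sigma)
  A <- rbind(c(0, rep(1, l)),
             cbind(1, K + diag(1 / g, l)))
  rhs <- c(0, y)
  sol <- tryCatch(solve(A, rhs), error = function(e) e)
  if (inherits(sol, "error")) {
    stop(sprintf(paste0("KKT system is numerically singular ",
                        "(reciprocal condition estimate %.3e); ",
                        "increase sigma or decrease g"),
                 rcond_estimate(A)), call. = FALSE)
  }
  resid <- max(abs(A %*% sol - rhs))
  if (!is.finite(resid) || resid > 1e-6 * max(1, max(abs(y)))) {
    kap <- 1 / rcond_estimate(A)
    if (kap > 1e12) {
      stop(sprintf(paste0("KKT system ill-conditioned (condition estimate ",
                          "%.3e > 1e12); increase sigma or decrease g"), kap),
           call. = FALSE)
    }
  }
  structure(list(train_inputs = X, alpha = as.numeric(sol[-1]),
                 b = as.double(sol[1]), g = g, sigma = sigma),
            class = "lssvm")
}

rcond_estimate <- function(A) {
  tryCatch(1 / kappa(A, exact = FALSE), error = function(e) NA_real_)
}

#' Predict from a fitted LSSVM
#'
#' Evaluates the dual predictor `y(x) = sum_i alpha_i k(x, x_i) + b` over
#' the stored training rows, vectorized over query rows.
#'
#' @param object an `lssvm` model.
#' @param newdata numeric vector (one query) or matrix of query rows with
#'   the training feature count.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.lssvm <- function(object, newdata, ...) {
  nf <- ncol(object$train_inputs)
  if (is.null(dim(newdata))) {
    if (length(newdata) != nf) {
      stop(sprintf("query has %d features; model expects %d",
                   length(newdata), nf), call. = FALSE)
    }
    newdata <- matrix(newdata, nrow = 1L)
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nf) {
    stop(sprintf("query has %d features; model expects %d",
                 ncol(newdata), nf), call. = FALSE)
  }
  Kq <- cross_kernel(newdata, object$train_inputs, object$sigma)
  as.numeric(Kq %*% object$alpha + object$b)
}

#' @export
print.lssvm <- function(x, ...) {
  cat(sprintf("<lssvm: %d training rows, %d features, g = %g, sigma = %g>\n",
              nrow(x$train_inputs), ncol(x$train_inputs), x$g, x$sigma))
  invisible(x)
}

LSSVM_FORMAT_VERSION <- "1.0"

#' Serialize an LSSVM model to portable JSON
#'
#' The container stores the hyperparameters, bias, dual coefficients,
#' training inputs and (optionally) normalization statistics, plus a
#' format-version field.
#'
#' @param model an `lssvm`, or a `soft_sensor` wrapper.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
lssvm_write_json <- function(model, path) {
  if (inherits(model, "soft_sensor")) {
    payload <- list(
      format_version = LSSVM_FORMAT_VERSION,
      kind = "soft_sensor",
      g = model$model$g, sigma = model$model$sigma,
      b = model$model$b, alpha = model$model$alpha,
      train_inputs = model$model$train_inputs,
      feature_names = model$feature_names,
      target_name = model$target_name,
      norm_min = as.list(model$stats$min),
      norm_max = as.list(model$stats$max))
  } else {
    stopifnot(inherits(model, "lssvm"))
    payload <- list(
      format_version = LSSVM_FORMAT_VERSION,
      kind = "lssvm",
      g = model$g, sigma = model$sigma,
      b = model$b, alpha = model$alpha,
      train_inputs = model$train_inputs)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized LSSVM (or soft-sensor) model
#'
#' @param path JSON file written by [lssvm_write_json()].
#' @return An `lssvm` or `soft_sensor` object.
#' @export
lssvm_read_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version)) {
    stop("not a serialized lssvm model: missing format_version",
         call. = FALSE)
  }
  core <- structure(list(train_inputs = as.matrix(obj$train_inputs),
                         alpha = as.numeric(obj$alpha),
                         b = as.double(obj$b),
                         g = as.double(obj$g),
                         sigma = as.double(obj$sigma)),
                    class = "lssvm")
  if (identical(obj$kind, "soft_sensor")) {
    stats <- structure(list(min = unlist(obj$norm_min),
                            max = unlist(obj$norm_max)),
                       class = "norm_stats")
    new_soft_sensor(core, stats, obj$feature_names, obj$target_name)
  } else {
    core
  }
}
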