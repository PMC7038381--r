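#' One-hot encoding of class labels
#'
#' Builds the `N x C` target matrix `T` used by the ELM/KELM ridge solves:
#' row `i` is the indicator of sample `i`'s class. Classes are ordered
#' lexicographically so the encoding is deterministic.
#'
#' @param labels vector of class identifiers (coerced to character).
#' @return list with `classes` (sorted unique labels), `T` (`N x C`
#'   one-hot matrix) and `y` (integer class index per sample).
#' @examples
#' one_hot_encode(c("b", "a", "b"))$T
#' @export
one_hot_encode <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("'labels' is empty")
  classes <- sort(unique(labels))
  y <- match(labels, classes)
  T <- matrix(0, nrow = length(labels), ncol = length(classes),
              dimnames = list(NULL, classes))
  T[cbind(seq_along(labels), y)] <- 1
  list(classes = classes, T = T, y = y)
}

# internal: symmetric positive-definite solve via Cholesky (never an
# explicit inverse)
solve_spd <- function(A, B) {
  R <- tryCatch(chol(A), error = function(e)
    stop("SPD solve failed (matrix not positive definite beyond ",
         "regularization): ", conditionMessage(e)))
  backsolve(R, backsolve(R, B, transpose = TRUE))
}

# internal: pairwise squared Euclidean distances between rows of A and B,
# by direct differencing (precision over speed; N is small here)
cross_sqdist <- function(A, B) {
  out <- matrix(0, nrow(A), nrow(B))
  for (q in seq_len(nrow(A))) {
    D <- B - matrix(A[q, ], nrow(B), ncol(B), byrow = TRUE)
    out[q, ] <- rowSums(D * D)
  }
  out
}

# internal: kernel matrix between rows of A and rows of B. The RBF uses
# the extreme-learning-machine literature convention exp(-||u-v||^2 /
# theta) (kernel width directly in the denominator), which differs from
# the 2*sigma^2 form of the FSE feature kernel.
kernel_matrix <- function(A, B, kernel, theta) {
  switch(kernel,
         rbf = exp(-cross_sqdist(A, B) / theta),
         linear = A %*% t(B),
         stop("kernel '", kernel, "' is not implemented"))
}

#' Kernel extreme learning machine (KELM) classifier
#'
#' Fits the kernelized ridge form of the extreme learning machine: with
#' kernel matrix `K` (`K_ij = k(x_i, x_j)`) and one-hot targets `T`, the
#' decision function for a query `x` is
#' \deqn{f(x) = [k(x, x_1), \ldots, k(x, x_N)] \, (K + I/\mu)^{-1} T.}
#' The dual coefficients `(K + I/mu)^{-1} T` are obtained by a symmetric
#' positive-definite (Cholesky) solve. Training is deterministic: no
#' random hidden layer is involved.
#'
#' @param x `N x p` numeric feature matrix (rows = samples).
#' @param labels class identifier per row.
#' @param mu regularization coefficient (larger = weaker ridge;
#'   default 1000).
#' @param theta RBF kernel width (default 10); the kernel is
#'   `exp(-||u - v||^2 / theta)`, the usual kernel-ELM parameterization.
#' @param kernel `"rbf"` or `"linear"` (plain inner product).
#' @return object of class `kelm`: list with `training_features`,
#'   `dual_coefficients` (`N x C`), `encoding`, `mu`, `theta`, `kernel`.
#' @seealso [predict.kelm()], [elm()]
#' @examples
#' x <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 5), 10))
#' fit <- kelm(x, rep(c("a", "b"), each = 10), mu = 1000, theta = 1)
#' predict(fit, x)$labels
#' @export
kelm <- function(x, labels, mu = 1000, theta = 10,
                 kernel = c("rbf", "linear")) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("'x' contains non-finite values")
  if (!is.numeric(mu) || mu <= 0) stop("'mu' must be positive")
  if (!is.numeric(theta) || theta <= 0) stop("'theta' must be positive")
  enc <- one_hot_encode(labels)
  if (length(enc$y) != nrow(x)) stop("'labels' length != nrow(x)")
  N <- nrow(x)
  K <- kernel_matrix(x, x, kernel, theta)
  A <- solve_spd(K + diag(1 / mu, N), enc$T)
  structure(list(training_features = x, dual_coefficients = A,
                 encoding = enc, mu = mu, theta = theta, kernel = kernel),
            class = "kelm")
}

# internal: deterministic argmax over score columns, ties to the lowest
# class index
argmax_labels <- function(scores, classes) {
  classes[max.col(scores, ties.method = "first")]
}

#' Predict classes with a fitted KELM
#'
#' @param object a [kelm()] fit.
#' @param newdata `Q x p` matrix of query features (`p` as in training).
#' @param ... unused.
#' @return list with `scores` (`Q x C` matrix) and `labels` (length-`Q`
#'   character vector; argmax per row, ties broken toward the lowest
#'   class index).
#' @export
predict.kelm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  p <- ncol(object$training_features)
  if (ncol(newdata) != p)
    stop("feature width mismatch: model expects ", p, ", got ",
         ncol(newdata))
  Kq <- kernel_matrix(newdata, object$training_features, object$kernel,
                      object$theta)
  scores <- Kq %*% object$dual_coefficients
  colnames(scores) <- object$encoding$classes
  list(scores = scores,
       labels = argmax_labels(scores, object$encoding$classes))
}

#' @export
print.kelm <- function(x, ...) {
  cat(sprintf("<kelm> %d training samples, %d features, %d classes (%s, mu = %g, theta = %g)\n",
              nrow(x$training_features), ncol(x$training_features),
              length(x$encoding$classes), x$kernel, x$mu, x$theta))
  invisible(x)
}
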