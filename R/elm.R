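#' Extreme learning machine (ELM) classifier
#'
#' Single-hidden-layer feed-forward network whose input weights `W`
#' (`L x p`) and biases `b` are drawn at random (uniform on `[-1, 1]`,
#' controlled by `seed`) and whose output weights `beta` are the closed
#' ridge solution. With hidden output `H = g(X W' + b)` and one-hot
#' targets `T`, the solve uses whichever form matches the shape of the
#' problem:
#' \deqn{\beta = (H'H + I_L/\mu)^{-1} H' T \quad (N \ge L)}
#' \deqn{\beta = H'(H H' + I_N/\mu)^{-1} T \quad (N < L)}
#' The two closed forms coincide (up to the ridge) and are both available
#' for cross-checking via `force_branch`.
#'
#' @param x `N x p` numeric feature matrix.
#' @param labels class identifier per row.
#' @param L number of hidden neurons (default 100).
#' @param mu regularization coefficient (default 1000).
#' @param activation `"sigmoid"` (default), `"tanh"` or `"relu"`.
#' @param seed integer seed for the random input layer.
#' @param force_branch `NULL` (choose by `N >= L`) or one of
#'   `"primal"`/`"dual"` to force a branch (testing aid).
#' @return object of class `elm`: list with `W`, `b`, `beta`, `encoding`,
#'   `L`, `mu`, `activation`, `seed`.
#' @seealso [predict.elm()], [kelm()]
#' @examples
#' x <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 4), 10))
#' fit <- elm(x, rep(c("a", "b"), each = 10), L = 20, seed = 1)
#' predict(fit, x)$labels
#' @export
elm <- function(x, labels, L = 100, mu = 1000, activation = "sigmoid",
                seed = 1, force_branch = NULL) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("'x' contains non-finite values")
  if (!is.numeric(L) || L < 1) stop("'L' must be a positive integer")
  L <- as.integer(L)
  if (!is.numeric(mu) || mu <= 0) stop("'mu' must be positive")
  activation <- match.arg(activation, c("sigmoid", "tanh", "relu"))
  enc <- one_hot_encode(labels)
  if (length(enc$y) != nrow(x)) stop("'labels' length != nrow(x)")
  N <- nrow(x); p <- ncol(x)
  rng <- local_rng(seed)
  W <- matrix(stats::runif(L * p, -1, 1), nrow = L)
  b <- stats::runif(L, -1, 1)
  rng()  # restore RNG state
  H <- elm_hidden(x, W, b, activation)
  branch <- if (is.null(force_branch)) {
    if (N >= L) "primal" else "dual"
  } else match.arg(force_branch, c("primal", "dual"))
  beta <- if (branch == "primal") {
    solve_spd(crossprod(H) + diag(1 / mu, L), crossprod(H, enc$T))
  } else {
    t(H) %*% solve_spd(tcrossprod(H) + diag(1 / mu, N), enc$T)
  }
  structure(list(W = W, b = b, beta = beta, encoding = enc, L = L,
                 mu = mu, activation = activation, seed = seed,
                 branch = branch),
            class = "elm")
}

# internal: hidden-layer output H = g(x W' + b)
elm_hidden <- function(x, W, b, activation) {
  A <- x %*% t(W) + matrix(b, nrow(x), length(b), byrow = TRUE)
  switch(activation,
         sigmoid = 1 / (1 + exp(-A)),
         tanh = tanh(A),
         relu = pmax(A, 0))
}

# internal: run code under a temporary seed; returns a restorer
local_rng <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
    invisible(NULL)
  }
}

#' Predict classes with a fitted ELM
#'
#' @param object an [elm()] fit.
#' @param newdata `Q x p` matrix of query features.
#' @param ... unused.
#' @return list with `scores` (`Q x C`) and `labels` (argmax per row,
#'   ties toward the lowest class index).
#' @export
predict.elm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$W))
    stop("feature width mismatch: model expects ", ncol(object$W),
         ", got ", ncol(newdata))
  H <- elm_hidden(newdata, object$W, object$b, object$activation)
  scores <- H %*% object$beta
  colnames(scores) <- object$encoding$classes
  list(scores = scores,
       labels = argmax_labels(scores, object$encoding$classes))
}

#' @export
print.elm <- function(x, ...) {
  cat(sprintf("<elm> L = %d hidden neurons (%s), %d classes, mu = %g [%s branch]\n",
              x$L, x$activation, length(x$encoding$classes), x$mu, x$branch))
  invisible(x)
}
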