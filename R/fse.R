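#' Radial basis function kernel
#'
#' Evaluates the Gaussian (RBF) kernel
#' \deqn{k(u, v) = \exp\left(-\frac{\|u - v\|_2^2}{2\sigma^2}\right)}
#' used throughout the FSE/KBM feature extractors. The value lies in
#' `(0, 1]` and equals 1 exactly when `u == v`.
#'
#' @param u,v numeric vectors of equal length.
#' @param sigma kernel width, a positive scalar.
#' @return a scalar in `(0, 1]`.
#' @examples
#' rbf_kernel(c(3, 4), c(0, 0), sigma = 5)  # exp(-0.5)
#' @export
rbf_kernel <- function(u, v, sigma) {
  if (length(u) != length(v))
    stop("'u' and 'v' must have the same length (", length(u),
         " vs ", length(v), ")")
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("'sigma' must be a positive finite scalar")
  d <- u - v
  exp(-sum(d * d) / (2 * sigma^2))
}

#' Common-mode / specificity decomposition of an electrode pair
#'
#' Splits the responses of electrodes `i` and `j` into the shared
#' common-mode part `x_c = (x_i + x_j)/2` (driven by the excitation and
#' carrying little class information) and the specificity part
#' `x_s = (x_i - x_j)/2` (the class-informative half-difference). The
#' identities `x_i = x_c + x_s` and `x_j = x_c - x_s` hold exactly.
#'
#' @param X a sensor matrix (`m x d`) or [sensor_sample()].
#' @param i,j distinct row (electrode) indices.
#' @return list with elements `common_mode`, `specificity`, `i`, `j`.
#' @examples
#' d <- decompose_pair(rbind(c(2, 2), c(0, 0)), 1, 2)
#' d$common_mode  # (1, 1)
#' @export
decompose_pair <- function(X, i, j) {
  X <- as.matrix(X)
  m <- nrow(X)
  if (i == j) stop("invalid pair: i == j")
  if (i < 1L || i > m || j < 1L || j > m)
    stop("electrode index out of range 1..", m)
  xi <- X[i, ]
  xj <- X[j, ]
  list(common_mode = (xi + xj) / 2,
       specificity = (xi - xj) / 2,
       i = as.integer(i), j = as.integer(j))
}

# internal: validate an FSE/KBM kernel configuration
check_kernel <- function(sigma, kernel) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("'sigma' must be a positive finite scalar")
  kernel <- match.arg(kernel, c("rbf", "poly", "sigmoid"))
  if (kernel != "rbf")
    stop("kernel '", kernel, "' is not implemented; only 'rbf' is available")
  kernel
}

# internal: optional per-electrode (row) z-scoring
standardize_rows <- function(X) {
  mu <- rowMeans(X)
  sd <- apply(X, 1, stats::sd)
  sd[sd == 0] <- 1
  (X - mu) / sd
}

#' Feature specificity enhancement (FSE) transform
#'
#' Maps one sensor-array sample `X` (`m` electrodes by `d` time points) to
#' the pairwise kernel features `Z_ij = k(x_i, x_j)` for all ordered pairs
#' `i != j`. Because the RBF kernel depends only on the difference
#' `x_i - x_j`, any component common to all electrodes cancels exactly:
#' the features measure the specificity of each electrode pair, not the
#' shared excitation response. Feature length is `m(m-1)` (the kernel is
#' symmetric, so each unordered pair appears twice; set
#' `unique_pairs = TRUE` for the `m(m-1)/2` distinct values).
#'
#' @param X a sensor matrix (`m x d`, `m >= 2`) or [sensor_sample()].
#' @param sigma RBF kernel width (positive).
#' @param kernel kernel name; only `"rbf"` is implemented.
#' @param unique_pairs if `TRUE`, emit only pairs with `i < j`.
#' @param standardize if `TRUE`, z-score each electrode row before the
#'   kernel (off by default: raw responses are used as measured).
#' @return named numeric vector of length `m(m-1)` (or `m(m-1)/2`), names
#'   `Z_i_j`, with attribute `pairs` (two-column matrix of `(i, j)`).
#'   Ordering is row-major: `i = 1..m`, `j = 1..m`, `j != i`.
#' @examples
#' X <- matrix(rnorm(6 * 50), nrow = 6)
#' length(fse_transform(X, sigma = 10))  # 6 * 5 = 30
#' @export
fse_transform <- function(X, sigma, kernel = "rbf", unique_pairs = FALSE,
                          standardize = FALSE) {
  kernel <- check_kernel(sigma, kernel)
  X <- as.matrix(X)
  m <- nrow(X)
  if (m < 2L)
    stop("FSE needs at least 2 electrodes, got m = ", m)
  if (standardize) X <- standardize_rows(X)
  # Squared pair distances by direct row differencing. The Gram-matrix
  # shortcut is avoided: it cancels catastrophically under a large shared
  # offset and would break common-mode invariance at the 1e-12 level.
  d2 <- matrix(0, m, m)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      dd <- X[i, ] - X[j, ]
      d2[i, j] <- d2[j, i] <- sum(dd * dd)
    }
  }
  if (unique_pairs) {
    idx <- which(upper.tri(d2), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  } else {
    idx <- cbind(rep(seq_len(m), each = m), rep(seq_len(m), times = m))
    idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
  }
  z <- exp(-d2[idx] / (2 * sigma^2))
  names(z) <- paste0("Z_", idx[, 1], "_", idx[, 2])
  attr(z, "pairs") <- unname(idx)
  attr(z, "method") <- "fse"
  z
}

#' Kernel baseline method (KBM) transform
#'
#' Contrast method for FSE: applies the same RBF form to each electrode's
#' raw response against the origin, `Z_i = exp(-||x_i||^2 / (2 sigma^2))`,
#' for `i = 1..m`. Unlike FSE the common-mode component is retained, so a
#' shared offset changes the output; this is the property FSE removes.
#'
#' @inheritParams fse_transform
#' @return named numeric vector of length `m`, names `Z_i`.
#' @examples
#' kbm_transform(matrix(0, 2, 4), sigma = 1)  # both features 1
#' @export
kbm_transform <- function(X, sigma, kernel = "rbf", standardize = FALSE) {
  kernel <- check_kernel(sigma, kernel)
  X <- as.matrix(X)
  if (standardize) X <- standardize_rows(X)
  z <- exp(-rowSums(X * X) / (2 * sigma^2))
  names(z) <- paste0("Z_", seq_len(nrow(X)))
  attr(z, "method") <- "kbm"
  z
}

#' Transform every sample of a dataset into a feature table
#'
#' Applies [fse_transform()], [kbm_transform()], or the identity ("raw",
#' flattening each sample row-wise) to each sample of a dataset. The
#' transforms are unsupervised and per-sample: labels are never read.
#'
#' @param data a [labeled_dataset()].
#' @param method `"fse"`, `"kbm"` or `"raw"`.
#' @param sigma kernel width for `"fse"`/`"kbm"`.
#' @param ... further arguments passed to the per-sample transform.
#' @return object of class `feature_table`: list with `x` (`N x p` matrix,
#'   one row per sample, columns named after the features), `labels`,
#'   `method`, `sigma`.
#' @examples
#' d <- labeled_dataset(list(matrix(rnorm(8), 2), matrix(rnorm(8), 2)),
#'                      c("a", "b"))
#' transform_dataset(d, "fse", sigma = 1)$x
#' @export
transform_dataset <- function(data, method = c("fse", "kbm", "raw"),
                              sigma = 10, ...) {
  check_dataset(data)
  method <- match.arg(method)
  n <- n_samples(data)
  fn <- switch(method,
               fse = function(s) fse_transform(s, sigma = sigma, ...),
               kbm = function(s) kbm_transform(s, sigma = sigma, ...),
               raw = function(s) as.vector(t(as.matrix(s))))
  if (n == 0L) {
    x <- matrix(numeric(0), nrow = 0, ncol = 0)
  } else {
    rows <- lapply(data$samples, fn)
    p <- length(rows[[1]])
    if (any(vapply(rows, length, integer(1)) != p))
      stop("inconsistent sample shapes in dataset")
    x <- do.call(rbind, rows)
    colnames(x) <- names(rows[[1]])
    rownames(x) <- NULL
  }
  structure(list(x = x, labels = data$labels, method = method,
                 sigma = if (method == "raw") NA_real_ else sigma),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features (%s%s)\n",
              nrow(x$x), ncol(x$x), x$method,
              if (is.na(x$sigma)) "" else sprintf(", sigma = %g", x$sigma)))
  invisible(x)
}
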