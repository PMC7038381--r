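#' Leave-one-replicate-per-class-out split plan
#'
#' The nine-round protocol used for balanced factorial panels: every class
#' must have the same number of samples R (e.g. 3 concentrations x 3
#' replicates = 9). Round r holds out the r-th sample of every class
#' (samples within a class ordered by concentration then replicate), so on
#' a 63-sample, 7-class design each round trains on 56 samples and tests
#' on 7, and each sample is tested exactly once.
#'
#' @param data a [labeled_dataset()].
#' @return object of class `split_plan` with `protocol = "loo_replicate"`:
#'   list of `splits`, each a list with integer `train` and `test`.
#' @export
make_loo_replicate_splits <- function(data) {
  check_dataset(data)
  labels <- data$labels
  counts <- table(labels)
  if (length(unique(as.integer(counts))) != 1L)
    stop("loo_replicate needs the same number of samples per class; got ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  R <- as.integer(counts[1])
  idx_by_class <- split(seq_along(labels), labels)
  ord <- function(ix) {
    if (!is.null(data$concentration) && !is.null(data$replicate))
      ix[order(data$concentration[ix], data$replicate[ix])]
    else ix
  }
  idx_by_class <- lapply(idx_by_class, ord)
  splits <- lapply(seq_len(R), function(r) {
    test <- sort(unname(vapply(idx_by_class, `[`, integer(1), r)))
    list(train = setdiff(seq_along(labels), test), test = test)
  })
  structure(list(splits = splits, protocol = "loo_replicate"),
            class = "split_plan")
}

#' Stratified four-fold split plan
#'
#' Partitions the dataset into four test groups of near-equal size (28,
#' 29, 28 and 29 on a 114-sample set) such that every class appears in
#' every group. Group assignment within a class is seeded-random; each
#' group first receives one sample of every class, then the remaining
#' samples fill the groups up to their target sizes.
#'
#' @param data a [labeled_dataset()].
#' @param seed integer seed for the assignment.
#' @return object of class `split_plan` with `protocol = "fourfold"`.
#' @export
make_fourfold_splits <- function(data, seed = 1) {
  check_dataset(data)
  labels <- data$labels
  n <- length(labels)
  counts <- table(labels)
  if (any(counts < 4L))
    stop("fourfold needs >= 4 samples per class; offending class: ",
         names(counts)[which.min(counts)])
  sizes <- rep(n %/% 4L, 4L)
  r <- n %% 4L
  if (r > 0L) sizes[c(2L, 4L, 3L, 1L)[seq_len(r)]] <- sizes[1] + 1L
  restore <- local_rng(seed)
  on.exit(restore())
  groups <- vector("list", 4L)
  remaining <- integer(0)
  for (cls in names(counts)) {
    ix <- sample(which(labels == cls))
    for (g in 1:4) groups[[g]] <- c(groups[[g]], ix[g])
    remaining <- c(remaining, ix[-(1:4)])
  }
  remaining <- sample(remaining)
  for (i in remaining) {
    capacity <- sizes - lengths(groups)
    g <- which(capacity > 0L)
    g <- if (length(g) > 1L) sample(g, 1L) else g
    groups[[g]] <- c(groups[[g]], i)
  }
  splits <- lapply(groups, function(te) {
    te <- sort(te)
    list(train = setdiff(seq_len(n), te), test = te)
  })
  structure(list(splits = splits, protocol = "fourfold"),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %s, %d splits; test sizes: %s\n", x$protocol,
              length(x$splits),
              paste(vapply(x$splits, function(s) length(s$test),
                           integer(1)), collapse = "/")))
  invisible(x)
}

# internal: fit the requested classifier on (x, y) and return a
# prediction closure. Baseline adapters delegate to their established
# implementations and error loudly when the package is missing.
fit_classifier <- function(classifier, x, y, mu, theta, elm_L, elm_seed) {
  need <- function(pkg) {
    if (!requireNamespace(pkg, quietly = TRUE))
      stop("classifier '", classifier, "' needs the '", pkg,
           "' package, which is not installed", call. = FALSE)
  }
  switch(classifier,
    kelm = {
      fit <- kelm(x, y, mu = mu, theta = theta)
      function(newx) predict(fit, newx)$labels
    },
    elm = {
      fit <- elm(x, y, L = elm_L, mu = mu, seed = elm_seed)
      function(newx) predict(fit, newx)$labels
    },
    svm = {
      need("e1071")
      fit <- e1071::svm(x, factor(y), kernel = "radial",
                        cost = 1000, gamma = 0.001)
      function(newx) as.character(predict(fit, newx))
    },
    rf = {
      need("randomForest")
      fit <- randomForest::randomForest(x, factor(y), ntree = 50)
      function(newx) as.character(predict(fit, newx))
    },
    lda = {
      need("MASS")
      fit <- MASS::lda(x, grouping = factor(y))
      function(newx) as.character(predict(fit, newx)$class)
    },
    nb = {
      need("e1071")
      fit <- e1071::naiveBayes(x, factor(y))
      function(newx) as.character(predict(fit, newx))
    },
    stop("unknown classifier '", classifier, "'")
  )
}

#' Evaluate a feature-method / classifier combination under a split plan
#'
#' For every split: extract features (an unsupervised, per-sample
#' operation — labels are never read), fit the classifier on the training
#' indices only, predict the held-out indices and record the accuracy.
#' Mean and standard deviation are reported in percent, as in standard
#' accuracy/STD model tables.
#'
#' @param data a [labeled_dataset()].
#' @param plan a `split_plan` from [make_loo_replicate_splits()] or
#'   [make_fourfold_splits()].
#' @param feature `"fse"`, `"kbm"` or `"raw"`.
#' @param classifier `"kelm"`, `"elm"`, or one of the baseline adapters
#'   `"svm"`, `"rf"`, `"lda"`, `"nb"`.
#' @param sigma FSE/KBM kernel width.
#' @param mu KELM/ELM regularization coefficient.
#' @param theta KELM kernel width.
#' @param elm_L,elm_seed hidden-layer size and seed for `"elm"`.
#' @return object of class `eval_result`: list with `per_split_accuracy`
#'   (fractions), `mean_accuracy` and `std_accuracy` (percent),
#'   `predictions` (per split) and `model_spec`.
#' @examples
#' \donttest{
#' d <- simulate_beverage_dataset(seed = 1)
#' r <- evaluate_model(d, make_loo_replicate_splits(d))
#' r$mean_accuracy
#' }
#' @export
evaluate_model <- function(data, plan,
                           feature = c("fse", "kbm", "raw"),
                           classifier = c("kelm", "elm", "svm", "rf",
                                          "lda", "nb"),
                           sigma = 10, mu = 1000, theta = 10,
                           elm_L = 100, elm_seed = 1) {
  check_dataset(data)
  if (!inherits(plan, "split_plan")) stop("'plan' must be a split_plan")
  feature <- match.arg(feature)
  classifier <- match.arg(classifier)
  ft <- transform_dataset(data, method = feature, sigma = sigma)
  acc <- numeric(length(plan$splits))
  preds <- vector("list", length(plan$splits))
  for (s in seq_along(plan$splits)) {
    tr <- plan$splits[[s]]$train
    te <- plan$splits[[s]]$test
    predict_fn <- fit_classifier(classifier, ft$x[tr, , drop = FALSE],
                                 ft$labels[tr], mu, theta, elm_L, elm_seed)
    got <- predict_fn(ft$x[te, , drop = FALSE])
    acc[s] <- mean(got == ft$labels[te])
    preds[[s]] <- data.frame(index = te, truth = ft$labels[te],
                             predicted = got)
  }
  structure(list(per_split_accuracy = acc,
                 mean_accuracy = 100 * mean(acc),
                 std_accuracy = if (length(acc) > 1) 100 * stats::sd(acc) else 0,
                 predictions = preds,
                 model_spec = list(feature = feature,
                                   classifier = classifier, sigma = sigma,
                                   mu = mu, theta = theta,
                                   protocol = plan$protocol)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s-%s (%s): accuracy %.2f%% (STD %.2f%%)\n",
              toupper(x$model_spec$feature),
              toupper(x$model_spec$classifier), x$model_spec$protocol,
              x$mean_accuracy, x$std_accuracy))
  invisible(x)
}

#' Parameter sensitivity sweep
#'
#' Re-evaluates one model over a grid of a single hyperparameter (the
#' FSE width `sigma`, the regularization coefficient `gamma` — i.e. the
#' ridge `mu` — or the KELM kernel width `theta`), all other parameters
#' fixed. Grid points where evaluation fails (e.g. a classifier that
#' cannot handle degenerate all-zero features at extreme widths) are
#' recorded as failed rows with the diagnostic message, not dropped.
#'
#' @param parameter `"sigma"`, `"gamma"` or `"theta"`.
#' @param grid numeric vector of parameter values (nonempty).
#' @param data a [labeled_dataset()].
#' @param plan a `split_plan`.
#' @param ... fixed arguments passed to [evaluate_model()].
#' @return data.frame with columns `parameter`, `value`, `mean_accuracy`,
#'   `std_accuracy`, `ok`, `note`.
#' @export
sensitivity_sweep <- function(parameter = c("sigma", "gamma", "theta"),
                              grid, data, plan, ...) {
  parameter <- match.arg(parameter)
  if (length(grid) == 0L) stop("'grid' is empty")
  fixed <- list(...)
  rows <- lapply(grid, function(v) {
    args <- c(list(data = data, plan = plan), fixed)
    args[[switch(parameter, sigma = "sigma", gamma = "mu",
                 theta = "theta")]] <- v
    res <- tryCatch(do.call(evaluate_model, args), error = identity)
    if (inherits(res, "error"))
      data.frame(parameter = parameter, value = v,
                 mean_accuracy = NA_real_, std_accuracy = NA_real_,
                 ok = FALSE, note = conditionMessage(res))
    else
      data.frame(parameter = parameter, value = v,
                 mean_accuracy = res$mean_accuracy,
                 std_accuracy = res$std_accuracy, ok = TRUE, note = "")
  })
  do.call(rbind, rows)
}
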