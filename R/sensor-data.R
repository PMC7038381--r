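#' Sensor-array response of one sample
#'
#' Wraps the raw responses of one measurement: an `m x d` numeric matrix with
#' one row per working electrode and one column per time point, plus the
#' electrode identifiers and optional class label.
#'
#' @param values numeric matrix, `m` electrodes (rows) by `d` time points
#'   (columns); all entries must be finite.
#' @param electrode_ids character vector of length `m`; defaults to
#'   `E1..Em`.
#' @param label optional class identifier (length-1 character).
#' @param sample_id optional sample identifier (length-1 character).
#'
#' @return An object of class `sensor_sample`: the matrix with attributes
#'   `electrode_ids`, `label` and `sample_id`.
#' @examples
#' s <- sensor_sample(matrix(rnorm(12), nrow = 2), label = "beer")
#' dim(s)
#' @export
sensor_sample <- function(values, electrode_ids = NULL, label = NULL,
                          sample_id = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  if (nrow(values) < 2L)
    stop("a sensor sample needs at least 2 electrodes (rows)")
  if (ncol(values) < 1L) stop("'values' needs at least 1 time point")
  if (!all(is.finite(values)))
    stop("'values' contains non-finite entries")
  if (is.null(electrode_ids))
    electrode_ids <- paste0("E", seq_len(nrow(values)))
  if (length(electrode_ids) != nrow(values))
    stop("'electrode_ids' length must equal the number of rows")
  structure(values,
            electrode_ids = as.character(electrode_ids),
            label = if (is.null(label)) NULL else as.character(label),
            sample_id = if (is.null(sample_id)) NULL else as.character(sample_id),
            class = c("sensor_sample", "matrix", "array"))
}

#' @export
print.sensor_sample <- function(x, ...) {
  cat(sprintf("<sensor_sample> %d electrodes x %d time points\n",
              nrow(x), ncol(x)))
  lab <- attr(x, "label")
  if (!is.null(lab)) cat("  label:", lab, "\n")
  cat("  electrodes:", paste(attr(x, "electrode_ids"), collapse = ", "), "\n")
  invisible(x)
}

#' Labelled collection of sensor samples
#'
#' @param samples list of matrices or [sensor_sample()] objects sharing the
#'   same dimensions and electrode order.
#' @param labels class identifier per sample.
#' @param concentration optional numeric fraction per sample.
#' @param replicate optional integer replicate index per sample.
#' @param provenance optional list recording how the dataset was produced
#'   (generator spec, seed, schema version).
#'
#' @return An object of class `labeled_dataset`: a list with elements
#'   `samples`, `labels`, `concentration`, `replicate`, `provenance`.
#' @examples
#' d <- labeled_dataset(list(matrix(0, 2, 3), matrix(1, 2, 3)), c("a", "b"))
#' length(d$samples)
#' @export
labeled_dataset <- function(samples, labels, concentration = NULL,
                            replicate = NULL, provenance = NULL) {
  if (!is.list(samples)) stop("'samples' must be a list")
  n <- length(samples)
  if (length(labels) != n)
    stop("'labels' length (", length(labels), ") != sample count (", n, ")")
  if (n > 0L) {
    dims <- vapply(samples, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("all samples must share the same m x d shape")
  }
  if (!is.null(concentration) && length(concentration) != n)
    stop("'concentration' length != sample count")
  if (!is.null(replicate) && length(replicate) != n)
    stop("'replicate' length != sample count")
  structure(list(samples = samples,
                 labels = as.character(labels),
                 concentration = concentration,
                 replicate = replicate,
                 provenance = provenance),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  n <- length(x$samples)
  cat(sprintf("<labeled_dataset> %d samples", n))
  if (n > 0L)
    cat(sprintf(", each %d x %d; %d classes",
                nrow(x$samples[[1]]), ncol(x$samples[[1]]),
                length(unique(x$labels))))
  cat("\n")
  invisible(x)
}

#' Number of samples in a dataset
#' @param x a `labeled_dataset`.
#' @export
n_samples <- function(x) length(x$samples)

# internal: check that every sample in a dataset is consistent
check_dataset <- function(data) {
  if (!inherits(data, "labeled_dataset"))
    stop("expected a 'labeled_dataset'")
  invisible(data)
}
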