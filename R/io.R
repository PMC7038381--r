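#' Write a dataset to disk
#'
#' Two formats: `"rds"` writes a single binary bundle (the fidelity
#' format: lossless, exact round trip), `"csv"` writes a directory bundle
#' with one delimited-text matrix per sample (17 significant digits, so
#' doubles round-trip exactly as well) plus a `manifest.json` holding
#' labels, concentrations, replicate ids, provenance and schema version.
#'
#' @param data a [labeled_dataset()].
#' @param path file (`"rds"`) or directory (`"csv"`) to write.
#' @param format `"rds"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, format = c("rds", "csv")) {
  check_dataset(data)
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(list(schema_version = 1L, data = data), path)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  n <- n_samples(data)
  files <- sprintf("sample_%03d.csv", seq_len(n))
  for (i in seq_len(n)) {
    M <- as.matrix(data$samples[[i]])
    txt <- apply(M, 1, function(r)
      paste(sprintf("%.17g", r), collapse = ","))
    writeLines(txt, file.path(path, files[i]))
  }
  manifest <- list(schema_version = 1L, files = files,
                   labels = data$labels,
                   concentration = data$concentration,
                   replicate = data$replicate,
                   electrode_ids = if (n > 0L)
                     attr(data$samples[[1]], "electrode_ids") else NULL,
                   provenance = data$provenance)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param path file or directory written by [write_dataset()].
#' @return a [labeled_dataset()].
#' @export
read_dataset <- function(path) {
  if (!dir.exists(path)) {
    bundle <- readRDS(path)
    if (is.null(bundle$schema_version))
      stop("not a dataset bundle: ", path)
    return(bundle$data)
  }
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  samples <- lapply(manifest$files, function(f) {
    lines <- readLines(file.path(path, f))
    M <- do.call(rbind, lapply(strsplit(lines, ","), as.numeric))
    sensor_sample(M, electrode_ids = manifest$electrode_ids)
  })
  labeled_dataset(samples, manifest$labels,
                  concentration = manifest$concentration,
                  replicate = manifest$replicate,
                  provenance = manifest$provenance)
}

#' Write a feature table as delimited text
#'
#' Columns: `sample`, `label`, then one column per feature (named
#' `Z_i_j` for FSE pairs, `Z_i` for KBM). Values use 17 significant
#' digits.
#'
#' @param ft a `feature_table` from [transform_dataset()].
#' @param path CSV file to write.
#' @return `path`, invisibly.
#' @export
write_features <- function(ft, path) {
  if (!inherits(ft, "feature_table")) stop("expected a 'feature_table'")
  df <- data.frame(sample = seq_len(nrow(ft$x)), label = ft$labels)
  x <- ft$x
  vals <- as.data.frame(matrix(sprintf("%.17g", x), nrow(x), ncol(x)))
  names(vals) <- colnames(ft$x)
  utils::write.csv(cbind(df, vals), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_features()]
#'
#' @param path CSV file.
#' @return a `feature_table` (with `method = NA`).
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  x <- as.matrix(df[, setdiff(names(df), c("sample", "label")),
                    drop = FALSE])
  structure(list(x = x, labels = as.character(df$label), method = NA,
                 sigma = NA_real_),
            class = "feature_table")
}

#' Serialize a trained classifier to a portable bundle
#'
#' Stores the model (training features, dual/output coefficients, class
#' list, configuration) with a schema version.
#'
#' @param model a [kelm()] or [elm()] fit.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, c("kelm", "elm"))) stop("expected a kelm/elm model")
  saveRDS(list(schema_version = 1L, type = class(model)[1],
               model = unclass(model)), path)
  invisible(path)
}

#' Load a classifier written by [save_model()]
#'
#' @param path file written by [save_model()].
#' @return the restored model.
#' @export
load_model <- function(path) {
  bundle <- readRDS(path)
  if (is.null(bundle$schema_version) || is.null(bundle$type))
    stop("not a model bundle: ", path)
  structure(bundle$model, class = bundle$type)
}
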