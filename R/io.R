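# File formats: one CSV per window (time_s, ecg, semg_r, semg_l) with a JSON
# sidecar (fs, label, seed), a manifest CSV listing windows, a features CSV,
# and JSON containers for models and evaluation reports. Plain-text formats
# throughout, chosen for inspectability.

#' Write a signal window to CSV + JSON sidecar
#'
#' @param record a three-channel [signal_record()].
#' @param path CSV file path; the sidecar is written next to it with the
#'   extension `.json`.
#' @param meta optional extra fields stored in the sidecar (e.g. a config
#'   hash).
#' @return `path`, invisibly.
#' @export
write_signal_window <- function(record, path, meta = list()) {
  stopifnot(inherits(record, "signal_record"))
  n <- length(record$samples[[1L]])
  # 17 significant digits so doubles round-trip bit-exactly through the CSV
  df <- data.frame(time_s = sprintf("%.17g", (seq_len(n) - 1L) / record$fs))
  for (ch in record$channels) df[[ch]] <- sprintf("%.17g", record$samples[[ch]])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- c(list(fs = record$fs, label = record$label,
                 channels = record$channels), meta)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Read a signal window from CSV + JSON sidecar
#'
#' Validates the column layout, checks for missing values, and cross-checks
#' the sampling rate implied by the time column against the sidecar.
#'
#' @param path CSV file path written by [write_signal_window()].
#' @return A [signal_record()].
#' @export
read_signal_window <- function(path) {
  if (!file.exists(path)) ff_stop_format(sprintf("no such file: %s", path))
  side_file <- sidecar_path(path)
  if (!file.exists(side_file))
    ff_stop_format(sprintf("missing JSON sidecar for %s", path))
  df <- read.csv(path)
  need <- c("time_s", "ecg", "semg_r", "semg_l")
  miss <- setdiff(need, names(df))
  if (length(miss))
    ff_stop_format(sprintf("%s: missing column(s) %s", path,
                           paste(miss, collapse = ", ")))
  if (anyNA(df[need]))
    ff_stop_format(sprintf("%s: NaN/NA values in signal columns", path))
  side <- jsonlite::read_json(side_file, simplifyVector = TRUE)
  fs_implied <- 1 / median(diff(df$time_s))
  if (abs(fs_implied - side$fs) / side$fs > 0.001)
    ff_stop_format(sprintf(
      "%s: sampling rate mismatch (sidecar %g Hz, time column implies %g Hz)",
      path, side$fs, fs_implied))
  label <- side$label
  label <- if (is.null(label) || is.na(label)) NA else as.numeric(label)
  signal_record(list(ecg = df$ecg, semg_r = df$semg_r, semg_l = df$semg_l),
                as.numeric(side$fs), label = label)
}

#' Write a dataset of windows plus a manifest
#'
#' @param records list of [signal_record()]s.
#' @param dir output directory (created if needed).
#' @param meta extra sidecar fields (e.g. config hash).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_dataset <- function(records, dir, meta = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(records), function(i) {
    f <- file.path(dir, sprintf("window_%04d.csv", i))
    write_signal_window(records[[i]], f, meta = meta)
    data.frame(window_id = i, file = basename(f), label = records[[i]]$label)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing `manifest.csv` and the window files.
#' @return List of [signal_record()]s in manifest order.
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) ff_stop_format(sprintf("no manifest.csv in %s", dir))
  manifest <- read.csv(mf)
  lapply(manifest$file, function(f) read_signal_window(file.path(dir, f)))
}

#' Serialize a fitted IPSO-SVM model to JSON
#'
#' Stores the support vectors, dual coefficients, biases, kernel width,
#' penalty, standardization statistics, fusion coefficients and metadata, so
#' a model can be reloaded and must predict identically.
#'
#' @param fit an `ipso_svm` from [fit_ipso_svm()].
#' @param path output JSON path.
#' @param meta extra metadata fields (e.g. seed, config hash).
#' @return `path`, invisibly.
#' @export
write_model <- function(fit, path, meta = list()) {
  stopifnot(inherits(fit, "ipso_svm"))
  subs <- lapply(fit$model$models, function(m)
    list(pair = m$pair, sv = m$sv, coef = m$coef, b = m$b,
         C = m$C, sigma = m$sigma))
  obj <- list(type = "ipso_svm", d = fit$d,
              scaler = list(mean = fit$scaler$mean, sd = fit$scaler$sd),
              C = fit$C, sigma = fit$sigma, columns = fit$columns,
              fitness = fit$fitness, iterations = fit$iterations,
              models = subs, meta = meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model written by [write_model()]
#'
#' @param path JSON path.
#' @return An `ipso_svm` object.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) ff_stop_format(sprintf("no such file: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "ipso_svm"))
    ff_stop_format(sprintf("%s is not a serialized ipso_svm model", path))
  subs <- lapply(seq_len(nrow_or_len(obj$models)), function(i) {
    m <- model_entry(obj$models, i)
    structure(list(sv = as.matrix(m$sv), coef = as.numeric(m$coef),
                   b = m$b, C = m$C, sigma = m$sigma,
                   pair = as.numeric(m$pair)),
              class = "binary_svm")
  })
  model <- structure(list(models = subs, classes = c(-1, 0, 1),
                          C = obj$C, sigma = obj$sigma),
                     class = "ovo_svm")
  structure(list(model = model, d = as.numeric(obj$d),
                 scaler = list(mean = as.numeric(obj$scaler$mean),
                               sd = as.numeric(obj$scaler$sd)),
                 history = NULL, iterations = obj$iterations,
                 fitness = obj$fitness, C = obj$C, sigma = obj$sigma,
                 columns = unlist(obj$columns)),
            class = "ipso_svm")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
model_entry <- function(x, i) if (is.data.frame(x)) lapply(x, `[[`, i) else x[[i]]

#' Write / read an evaluation report as JSON
#'
#' Round-trips losslessly: numeric fields are written at full precision.
#'
#' @param report an `evaluation_report` from [mccv()].
#' @param path JSON path.
#' @param meta extra metadata fields.
#' @return `path` (write) or the reconstructed `evaluation_report` (read).
#' @export
write_report <- function(report, path, meta = list()) {
  stopifnot(inherits(report, "evaluation_report"))
  obj <- unclass(report)
  obj$per_class_rate <- as.list(report$per_class_rate)  # keep state names
  obj$confusion <- as.data.frame(as.table(report$confusion))
  names(obj$confusion) <- c("truth", "predicted", "count")
  obj$meta <- meta
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cm <- matrix(0L, 3L, 3L, dimnames = list(c(-1, 0, 1), c(-1, 0, 1)))
  for (i in seq_len(nrow(obj$confusion)))
    cm[as.character(obj$confusion$truth[i]),
       as.character(obj$confusion$predicted[i])] <- obj$confusion$count[i]
  structure(list(
    classifier = obj$classifier, mean_rate = obj$mean_rate,
    per_class_rate = unlist(obj$per_class_rate),
    confusion = cm, rep_rates = as.numeric(obj$rep_rates),
    n_rep = obj$n_rep, test_fraction = obj$test_fraction,
    seed = obj$seed
  ), class = "evaluation_report")
}

#' Write a feature table CSV
#'
#' @param features data.frame from [extract_feature_table()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) ff_stop_format(sprintf("no such file: %s", path))
  df <- read.csv(path)
  miss <- setdiff(feature_names(), names(df))
  if (length(miss))
    ff_stop_format(sprintf("%s: missing feature column(s) %s", path,
                           paste(miss, collapse = ", ")))
  df
}
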