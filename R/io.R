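#' Read a labeled feature table from CSV or ARFF
#'
#' Reads the standard distribution layouts for pre-extracted wearable-sensor
#' feature tables: CSV with a header row, or ARFF with numeric attributes
#' and a nominal class attribute. Exactly one column is the class label —
#' the last column, or the one named by `label`. All feature columns are
#' coerced to numeric (a non-numeric feature column is an error naming the
#' column) and missing cells are imputed by the mean of the column's present
#' values.
#'
#' @param path file path.
#' @param format `"csv"`, `"arff"`, or `"auto"` (by file extension).
#' @param label optional name of the label column; defaults to the last
#'   column.
#' @return data.frame of numeric feature columns with a trailing factor
#'   column `label`.
#' @export
read_table <- function(path, format = c("auto", "csv", "arff"), label = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  }
  raw <- switch(format,
                csv = utils::read.csv(path, check.names = FALSE),
                arff = foreign::read.arff(path))
  stop_if_not(ncol(raw) >= 2, "table needs at least one feature column plus a label")
  if (is.null(label)) label <- names(raw)[ncol(raw)]
  stop_if_not(label %in% names(raw), "no column named '%s'", label)
  feats <- setdiff(names(raw), label)
  for (cn in feats) {
    v <- raw[[cn]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(as.character(v)))
      stop_if_not(!all(is.na(coerced)) &&
                    sum(is.na(coerced)) == sum(is.na(v) | as.character(v) == "?"),
                  "feature column '%s' is not numeric", cn)
      v <- coerced
    }
    if (anyNA(v)) v <- impute_missing(v)
    raw[[cn]] <- v
  }
  out <- raw[, c(feats, label)]
  names(out)[ncol(out)] <- "label"
  out$label <- factor(out$label)
  out
}

#' Write a labeled feature table to CSV or ARFF
#'
#' CSV carries the feature names as a header with the label last; ARFF
#' declares numeric attributes and a trailing nominal class attribute.
#'
#' @param data data.frame with numeric feature columns and a factor column
#'   `label`.
#' @param path output file path.
#' @param format `"csv"`, `"arff"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_table <- function(data, path, format = c("auto", "csv", "arff")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  }
  stop_if_not("label" %in% names(data), "data must carry a 'label' column")
  data <- data[, c(setdiff(names(data), "label"), "label")]
  if (format == "csv") {
    utils::write.csv(data, path, row.names = FALSE)
  } else {
    data$label <- factor(data$label)
    foreign::write.arff(data, path)
  }
  invisible(path)
}

#' Read / write multichannel recordings as CSV
#'
#' The recording layout is one row per sample: a time column `t`, the
#' channel columns (conventionally `ax, ay, az, gx, gy, gz`), and an
#' optional trailing `label` column with per-sample class labels.
#'
#' @param recording a [new_recording()] object.
#' @param path file path.
#' @param fs sampling rate; when `NULL` it is inferred from the median time
#'   step of the `t` column.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   a `recording` object.
#' @export
write_recording <- function(recording, path) {
  stop_if_not(inherits(recording, "recording"), "recording must be a recording")
  out <- recording$data
  if (!is.null(recording$labels)) out$label <- recording$labels
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path, fs = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE)
  stop_if_not("t" %in% names(raw), "recording CSV needs a time column 't'")
  labels <- NULL
  if ("label" %in% names(raw)) {
    labels <- factor(raw$label)
    raw$label <- NULL
  }
  if (is.null(fs)) {
    dt <- stats::median(diff(raw$t))
    stop_if_not(is.finite(dt) && dt > 0, "cannot infer the sampling rate from 't'")
    fs <- 1 / dt
  }
  new_recording(raw, fs, labels)
}

flatten_config <- function(config) {
  cfg <- unclass(config)
  cfg <- lapply(cfg, function(v) {
    if (inherits(v, "qlearn_params") || inherits(v, "reward_params")) unclass(v) else v
  })
  cfg
}

#' Write a run report as JSON
#'
#' Serializes everything needed to replay and inspect a search run: the
#' config echo (including seed), the per-iteration history, the final mask
#' as a bit-string and as a sorted 0-based index list, and the held-out
#' confusion matrix when the fit carries one. Wall-time fields are included
#' for information but are hardware-dependent and excluded from any
#' determinism comparison.
#'
#' @param run an `fs_run` or `feat_select` object.
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_run_report <- function(run, path) {
  stop_if_not(inherits(run, "fs_run"), "run must be an fs_run")
  report <- list(
    method = run$method,
    objective = run$objective_id,
    config = flatten_config(run$config),
    n_evaluations = run$n_evals,
    best = list(
      accuracy = run$best_fitness$accuracy,
      n_selected = run$best_fitness$n_selected,
      mask = mask_key(run$best_mask),
      indices = which(run$best_mask == 1L) - 1L),
    history = run$history)
  if (!is.null(run$confusion)) {
    report$confusion <- list(classes = rownames(run$confusion),
                             counts = unclass(unname(apply(run$confusion, 1, as.integer,
                                                           simplify = FALSE))))
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a run report written by [write_run_report()]
#'
#' @param path path to the JSON report.
#' @return The parsed report list (history as a data.frame).
#' @export
read_run_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep
}
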