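#' ROI time-series container
#'
#' A real-valued `n_rois x n_samples` matrix with its sampling rate and
#' ordered ROI labels; the pipeline's sole signal input.
#'
#' @param data Numeric matrix, rows = ROIs, columns = samples.
#' @param fs Sampling rate in Hz.
#' @param labels Character vector of unique ROI labels, one per row.
#'   Defaults to `roi_001 ...`.
#' @param subject_id Optional subject identifier.
#' @param group Optional group label (e.g. `"HC"`, `"BD"`).
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(data, fs, labels = NULL, subject_id = NA_character_,
                           group = NA_character_) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("'data' must be a numeric matrix (n_rois x n_samples)", call. = FALSE)
  }
  if (any(!is.finite(data))) stop("'data' contains non-finite values", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("'fs' must be a positive scalar (Hz)", call. = FALSE)
  }
  if (is.null(labels)) labels <- sprintf("roi_%03d", seq_len(nrow(data)))
  labels <- as.character(labels)
  if (length(labels) != nrow(data)) {
    stop("length(labels) (", length(labels), ") must equal nrow(data) (",
         nrow(data), ")", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("ROI labels must be unique; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels,
                 subject_id = subject_id, group = group),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %d ROIs x %d samples @ %g Hz (%.1f s)",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (!is.na(x$subject_id)) cat(sprintf("  subject %s", x$subject_id))
  if (!is.na(x$group)) cat(sprintf(" [%s]", x$group))
  cat("\n")
  invisible(x)
}

#' Write / read an ROI time-series container
#'
#' The binary container is R's native serialization holding the matrix plus
#' `fs` and `labels`; write-then-read is bit-exact. See
#' [write_timeseries_tsv()] for the delimited-text fallback.
#'
#' @param ts A [roi_timeseries()].
#' @param path File path (conventionally `.rds`).
#' @return `write_timeseries()` returns `path` invisibly; `read_timeseries()`
#'   returns the [roi_timeseries()].
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  saveRDS(ts, path, version = 2)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- readRDS(path)
  if (!inherits(obj, "roi_timeseries")) {
    stop("file '", path, "' does not contain an roi_timeseries container",
         call. = FALSE)
  }
  for (field in c("data", "fs", "labels")) {
    if (is.null(obj[[field]])) {
      stop("container '", path, "' is missing required field '", field, "'",
           call. = FALSE)
    }
  }
  obj
}

#' Delimited-text time-series round trip
#'
#' Text fallback: one row per ROI, header row of ROI labels transposed into a
#' first `roi` column, plus a JSON sidecar (`<path>.json`) carrying `fs`,
#' `subject_id` and `group`. Values survive the round trip to at least 1e-12
#' relative accuracy (full double precision is printed).
#'
#' @inheritParams write_timeseries
#' @export
write_timeseries_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  df <- data.frame(roi = ts$labels,
                   format(ts$data, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("roi", sprintf("s%d", seq_len(ncol(ts$data)) - 1L))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(fs = ts$fs, subject_id = ts$subject_id, group = ts$group)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_timeseries_tsv
#' @export
read_timeseries_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("sidecar '", sidecar, "' (attribute 'fs') is missing", call. = FALSE)
  }
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(side$fs)) stop("sidecar is missing attribute 'fs'", call. = FALSE)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- df[[1L]]
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  dimnames(mat) <- NULL
  roi_timeseries(mat, fs = as.numeric(side$fs), labels = labels,
                 subject_id = side$subject_id %||% NA_character_,
                 group = side$group %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
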