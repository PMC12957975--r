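#' ROI time-series container
#'
#' Holds one subject's regional time series: a numeric matrix with `T` rows
#' (time points) and `R` columns (regions of interest), plus ROI labels and a
#' subject identifier.
#'
#' @param data numeric `T x R` matrix, rows = time points, columns = ROIs.
#' @param subject_id character scalar.
#' @param roi_labels character vector of `R` ROI names; defaults to column
#'   names of `data` or `"roi_1" ... "roi_R"`.
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(data, subject_id = "subject", roi_labels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (anyNA(data) || !all(is.finite(data))) {
    stop("roi_timeseries: data contains missing or non-finite values")
  }
  if (is.null(roi_labels)) {
    roi_labels <- colnames(data)
    if (is.null(roi_labels)) roi_labels <- paste0("roi_", seq_len(ncol(data)))
  }
  if (length(roi_labels) != ncol(data)) {
    stop("roi_timeseries: roi_labels length must match the number of columns")
  }
  if (anyDuplicated(roi_labels)) {
    stop("roi_timeseries: duplicate ROI labels")
  }
  colnames(data) <- roi_labels
  structure(
    list(data = data, subject_id = as.character(subject_id),
         roi_labels = as.character(roi_labels)),
    class = "roi_timeseries"
  )
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> subject '%s': %d time points x %d ROIs\n",
              x$subject_id, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' @export
dim.roi_timeseries <- function(x) dim(x$data)

#' Condition ROI time series
#'
#' Standardizes every ROI column to mean 0 and unit standard deviation.  All
#' downstream network construction assumes conditioned input: z-scored
#' columns make the sparse-regression penalty scale-free and give every
#' node-wise design an identical diagonal Gram (`T - 1`).
#'
#' @param ts a [roi_timeseries].
#' @return A conditioned [roi_timeseries].
#' @export
condition_timeseries <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  x <- ts$data
  if (nrow(x) < 3) stop("condition_timeseries: need at least 3 time points")
  sds <- apply(x, 2, sd)
  bad <- which(sds < 1e-12)
  if (length(bad) > 0) {
    stop(sprintf("condition_timeseries: zero-variance ROI(s): %s",
                 paste(ts$roi_labels[bad], collapse = ", ")))
  }
  z <- scale(x, center = TRUE, scale = TRUE)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  out <- ts
  out$data <- z
  colnames(out$data) <- ts$roi_labels
  attr(out, "conditioned") <- TRUE
  out
}

is_conditioned <- function(ts) isTRUE(attr(ts, "conditioned"))

ensure_conditioned <- function(ts) {
  if (is_conditioned(ts)) ts else condition_timeseries(ts)
}

#' Read ROI time series from delimited text
#'
#' Expects a header row of ROI labels followed by a numeric body, one row per
#' time point (tab- or comma-delimited; detected from the header).
#'
#' @param path file path.
#' @param subject_id subject identifier; defaults to the file name without
#'   extension.
#' @return A [roi_timeseries].
#' @export
read_timeseries <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("read_timeseries: no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("read_timeseries: file has no data rows: ", path)
  delim <- if (grepl("\t", lines[1])) "\t" else ","
  labels <- trimws(strsplit(lines[1], delim, fixed = TRUE)[[1]])
  if (anyDuplicated(labels)) {
    stop("read_timeseries: duplicate ROI labels in header of ", path)
  }
  R <- length(labels)
  body <- strsplit(lines[-1], delim, fixed = TRUE)
  n_fields <- lengths(body)
  if (any(n_fields != R)) {
    bad <- which(n_fields != R)[1]
    stop(sprintf("read_timeseries: line %d of %s has %d fields, expected %d",
                 bad + 1L, path, n_fields[bad], R))
  }
  vals <- suppressWarnings(vapply(body, as.numeric, numeric(R)))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 2, any))[1]
    stop(sprintf("read_timeseries: non-numeric or missing cell on line %d of %s",
                 bad + 1L, path))
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]+$", "", basename(path))
  }
  roi_timeseries(t(vals), subject_id = subject_id, roi_labels = labels)
}

#' Write ROI time series as delimited text
#'
#' @param ts a [roi_timeseries].
#' @param path output file path.
#' @param digits significant digits to print (values round-trip bit-exactly
#'   at the default full precision).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path, digits = 17) {
  stopifnot(inherits(ts, "roi_timeseries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(ts$roi_labels, collapse = "\t"), con)
  body <- apply(ts$data, 1, function(row) {
    paste(formatC(row, digits = digits, format = "g"), collapse = "\t")
  })
  writeLines(body, con)
  invisible(path)
}
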