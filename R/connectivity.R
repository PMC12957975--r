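#' Connectivity matrix container
#'
#' An `R x R` symmetric, zero-diagonal edge-weight matrix in Fisher-z units,
#' tagged with the construction method (`"PC"`, `"SR"`, `"GSR"`), the
#' regularization weight (absent for PC), and a subject id.  Symmetry, zero
#' diagonal, and finiteness are asserted on construction.
#'
#' @param values numeric `R x R` matrix.
#' @param method one of `"PC"`, `"SR"`, `"GSR"`.
#' @param lambda regularization weight (`NA` for PC).
#' @param subject_id subject identifier.
#' @param roi_labels optional ROI labels.
#' @return An object of class `connectivity_matrix` (a matrix with
#'   attributes).
#' @export
connectivity_matrix <- function(values, method = c("PC", "SR", "GSR"),
                                lambda = NA_real_, subject_id = "subject",
                                roi_labels = NULL) {
  method <- match.arg(method)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("connectivity_matrix: not square")
  if (!all(is.finite(values))) stop("connectivity_matrix: non-finite entries")
  if (max(abs(values - t(values))) > 1e-10) {
    stop("connectivity_matrix: not symmetric")
  }
  if (max(abs(diag(values))) > 1e-12) {
    stop("connectivity_matrix: diagonal must be exactly zero")
  }
  values <- (values + t(values)) / 2
  diag(values) <- 0
  if (!is.null(roi_labels)) dimnames(values) <- list(roi_labels, roi_labels)
  structure(values, class = c("connectivity_matrix", "matrix"),
            method = method, lambda = lambda, subject_id = subject_id)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  lam <- attr(x, "lambda")
  cat(sprintf("<connectivity_matrix> %s%s, subject '%s', %d ROIs, %d nonzero edges\n",
              attr(x, "method"),
              if (is.na(lam)) "" else sprintf(" (lambda = %.4g)", lam),
              attr(x, "subject_id"), nrow(x),
              sum(x[upper.tri(x)] != 0)))
  invisible(x)
}

# Fisher r-to-z with clipping: atanh is undefined at +-1, and regression
# weights can exceed 1 in magnitude.  Values with |v| >= 1 - 1e-7 are clipped.
fisher_z <- function(v) {
  cap <- 1 - 1e-7
  atanh(pmin(pmax(v, -cap), cap))
}

#' Write a connectivity matrix as delimited text
#'
#' One-line `#` header records method, lambda, and subject id; the body is a
#' tab-delimited `R x R` matrix.
#'
#' @param cm a [connectivity_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(cm, path) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# method=%s lambda=%s subject_id=%s",
                     attr(cm, "method"),
                     format(attr(cm, "lambda")), attr(cm, "subject_id")), con)
  body <- apply(unclass(cm), 1, function(row) {
    paste(formatC(row, digits = 17, format = "g"), collapse = "\t")
  })
  writeLines(body, con)
  invisible(path)
}

#' Read a connectivity matrix written by [write_connectivity()]
#'
#' @param path input path.
#' @return A [connectivity_matrix].
#' @export
read_connectivity <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  if (!startsWith(hdr, "#")) stop("read_connectivity: missing header line")
  get_field <- function(key) {
    m <- regmatches(hdr, regexec(paste0(key, "=(\\S+)"), hdr))[[1]]
    if (length(m) < 2) NA_character_ else m[2]
  }
  vals <- do.call(rbind, lapply(strsplit(lines[-1], "\t", fixed = TRUE),
                                as.numeric))
  lam <- suppressWarnings(as.numeric(get_field("lambda")))
  connectivity_matrix(vals, method = get_field("method"), lambda = lam,
                      subject_id = get_field("subject_id"))
}
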