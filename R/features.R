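#' Upper-triangle feature index map
#'
#' Connection features are ordered `(1,2), (1,3), ..., (1,R), (2,3), ...`
#' (pairs `i < j`, row-major).  The map is a bijection between feature
#' columns and ROI pairs.
#'
#' @param R number of ROIs.
#' @return data.frame with columns `col`, `roi_i`, `roi_j`.
#' @export
upper_triangle_map <- function(R) {
  p <- all_pairs(R)
  data.frame(col = seq_len(nrow(p)), roi_i = p[, 1], roi_j = p[, 2])
}

#' Vectorize a connectivity matrix into a feature row
#'
#' @param cm a symmetric zero-diagonal matrix ([connectivity_matrix] or
#'   plain matrix).
#' @return Numeric vector of length `R(R-1)/2` in the order of
#'   [upper_triangle_map()].
#' @export
vectorize_upper_triangle <- function(cm) {
  m <- unclass(as.matrix(cm))
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-10) {
    stop("vectorize_upper_triangle: input must be a symmetric square matrix")
  }
  # column-major lower triangle enumerates pairs (i<j) in row-major order
  m[lower.tri(m)]
}

#' Rebuild a symmetric matrix from a feature row
#'
#' Inverse of [vectorize_upper_triangle()].
#'
#' @param f feature vector of length `R(R-1)/2`.
#' @param R number of ROIs.
#' @return Symmetric `R x R` matrix with zero diagonal.
#' @export
matrix_from_features <- function(f, R) {
  if (length(f) != R * (R - 1) / 2) {
    stop("matrix_from_features: length must be R(R-1)/2")
  }
  m <- matrix(0, R, R)
  m[lower.tri(m)] <- f
  m + t(m)
}

cohort_features <- function(networks) {
  do.call(rbind, lapply(networks, vectorize_upper_triangle))
}

#' LASSO feature selection
#'
#' Fits an l1-penalized linear regression of the -1/+1 labels on
#' column-standardized features (objective
#' `1/(2n) * ||y - b0 - F w||^2 + lambda * ||w||_1`, with an intercept via
#' centering) and returns the columns with nonzero coefficients.
#' Deterministic for fixed input.
#'
#' @param features numeric subjects x connections matrix.
#' @param labels -1/+1 vector.
#' @param lambda penalty on the standardized-feature scale, `lambda > 0`.
#' @param tol,max_iter solver controls.
#' @return Integer vector of selected column indices (possibly empty).
#' @export
lasso_select <- function(features, labels, lambda, tol = 1e-8,
                         max_iter = 10000L) {
  features <- as.matrix(features)
  labels <- as.numeric(labels)
  stopifnot(lambda > 0, nrow(features) == length(labels))
  if (sum(labels > 0) < 2 || sum(labels < 0) < 2) {
    stop("lasso_select: need at least 2 subjects per class")
  }
  n <- nrow(features)
  sds <- apply(features, 2, sd)
  live <- sds >= 1e-12
  Fs <- matrix(0, n, ncol(features))
  Fs[, live] <- scale(features[, live, drop = FALSE])
  yc <- labels - mean(labels)
  fit <- cpp_lasso_path(Fs, yc, lambda * n, tol * n, as.integer(max_iter))
  which(drop(fit$coef) != 0)
}

#' Train a soft-margin linear SVM
#'
#' Hinge-loss linear SVM (fixed regularization `C`) solved by deterministic
#' dual coordinate descent with the bias carried on an augmented constant
#' feature.  Returns the primal weights used for discriminative-connection
#' aggregation.
#'
#' @param x numeric subjects x features matrix (already selected features).
#' @param labels -1/+1 vector; both classes must be present.
#' @param C soft-margin cost (default 1).
#' @param tol dual projected-gradient tolerance.
#' @param max_pass maximum passes over the data.
#' @return list of class `linear_svm`: `w` (weights), `b` (bias).
#' @export
train_linear_svm <- function(x, labels, C = 1, tol = 1e-6, max_pass = 5000L) {
  x <- as.matrix(x)
  labels <- as.numeric(labels)
  stopifnot(nrow(x) == length(labels), all(labels %in% c(-1, 1)))
  if (length(unique(labels)) < 2) {
    stop("train_linear_svm: both classes must be present")
  }
  if (ncol(x) == 0) stop("train_linear_svm: empty feature selection")
  fit <- cpp_svm_linear(x, labels, C, tol, as.integer(max_pass))
  structure(list(w = drop(fit$w), b = fit$b, C = C), class = "linear_svm")
}

#' @export
predict.linear_svm <- function(object, newdata, type = c("class", "decision"),
                               ...) {
  type <- match.arg(type)
  newdata <- matrix(as.numeric(newdata), ncol = length(object$w))
  dec <- drop(newdata %*% object$w) + object$b
  if (type == "decision") dec else ifelse(dec >= 0, 1L, -1L)
}
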