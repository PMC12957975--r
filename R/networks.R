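#' Pearson correlation (PC) network
#'
#' Pairwise Pearson correlations between all ROI time series, Fisher
#' r-to-z transformed (`atanh`), assembled into a symmetric matrix with zero
#' diagonal.  Correlations with `|r| >= 1` between distinct ROIs are clipped
#' to `1 - 1e-7` in magnitude before the transform.
#'
#' @param ts a [roi_timeseries] (conditioned automatically).
#' @return A [connectivity_matrix] with method `"PC"`.
#' @export
pearson_network <- function(ts) {
  ts <- ensure_conditioned(ts)
  r <- cor(ts$data)
  z <- fisher_z(r)
  diag(z) <- 0
  connectivity_matrix(z, method = "PC", subject_id = ts$subject_id,
                      roi_labels = ts$roi_labels)
}

# Gram matrix of a conditioned subject: crossprod of the z-scored signal.
# Diagonal entries equal T - 1 exactly, which the solvers exploit.
subject_gram <- function(ts) {
  crossprod(ts$data)
}

gram_cube <- function(subjects) {
  R <- ncol(subjects[[1]]$data)
  G <- array(0, dim = c(R, R, length(subjects)))
  for (i in seq_along(subjects)) G[, , i] <- subject_gram(subjects[[i]])
  G
}

#' Smallest all-zero penalty for a subject's sparse-representation network
#'
#' @param ts a [roi_timeseries] (conditioned automatically).
#' @return The maximum over ROIs of the node-wise l1 `lambda_max`; at any
#'   `lambda` at or above it [sr_network()] is exactly zero.
#' @export
lambda_max_sr <- function(ts) {
  ts <- ensure_conditioned(ts)
  G <- subject_gram(ts)
  diag(G) <- 0
  max(abs(G))
}

#' Smallest all-zero penalty for a cohort's group sparse network
#'
#' @param subjects a [cohort] or list of [roi_timeseries] (conditioned
#'   automatically).
#' @return The maximum over ROIs of the group-problem `lambda_max`.
#' @export
lambda_max_gsr_cohort <- function(subjects) {
  if (inherits(subjects, "cohort")) subjects <- subjects$subjects
  subjects <- lapply(subjects, ensure_conditioned)
  cpp_gsr_lambda_max(gram_cube(subjects))
}

finalize_connectivity <- function(raw, method, lambda, subject_id, roi_labels) {
  fin <- cpp_finalize_network(raw)
  cm <- connectivity_matrix(fin$matrix, method = method, lambda = lambda,
                            subject_id = subject_id, roi_labels = roi_labels)
  attr(cm, "n_clipped") <- fin$n_clipped
  cm
}

#' Sparse representation (SR) network
#'
#' For each ROI `r`, regresses its signal on all other ROIs under an l1
#' penalty; the coefficients fill row `r` of a raw asymmetric weight matrix.
#' Nonzero weights are Fisher z-transformed (with clipping), then the matrix
#' is symmetrized by bidirectional averaging with zero diagonal.  Sparser
#' than the PC network for any `lambda` above the solver's noise floor.
#'
#' @param ts a [roi_timeseries] (conditioned automatically).
#' @param lambda l1 penalty weight, `lambda > 0`.
#' @param tol solver KKT tolerance (absolute, on the gradient scale `T - 1`).
#' @param max_iter maximum coordinate-descent sweeps per ROI.
#' @return A [connectivity_matrix] with method `"SR"`.
#' @export
sr_network <- function(ts, lambda, tol = 1e-8, max_iter = 10000L) {
  stopifnot(lambda > 0)
  ts <- ensure_conditioned(ts)
  G <- array(subject_gram(ts), dim = c(ncol(ts$data), ncol(ts$data), 1))
  path <- cpp_network_path(G, lambda, tol * (nrow(ts$data) - 1),
                           as.integer(max_iter))
  raw <- path$raw[[1]][, , 1]
  finalize_connectivity(raw, "SR", lambda, ts$subject_id, ts$roi_labels)
}

#' Group sparse representation (GSR) network set
#'
#' Solves, for each ROI, the joint l2,1-penalized regression across all
#' provided subjects, so that every subject's network shares the same
#' predictor support per ROI (row-sparsity is enforced jointly).  Each
#' subject's raw weight matrix is Fisher z-transformed on its nonzeros,
#' symmetrized by bidirectional averaging, and zero-diagonal.
#'
#' @param subjects a [cohort] or list of [roi_timeseries].
#' @param lambda l2,1 penalty weight, `lambda > 0`.
#' @param tol solver KKT tolerance (relative; scaled by `T - 1` internally).
#' @param max_iter maximum block-coordinate sweeps per ROI.
#' @param keep_raw also return the pre-symmetrization raw weight matrices.
#' @return A list of class `gsr_network_set`: `networks` (one
#'   [connectivity_matrix] per subject), `support` (per-ROI predictor index
#'   sets shared across subjects, usable with [encode_new_subject()]),
#'   `lambda`, and optionally `raw`.
#' @export
gsr_network_set <- function(subjects, lambda, tol = 1e-8, max_iter = 10000L,
                            keep_raw = FALSE) {
  stopifnot(lambda > 0)
  if (inherits(subjects, "cohort")) subjects <- subjects$subjects
  subjects <- lapply(subjects, ensure_conditioned)
  Tn <- nrow(subjects[[1]]$data)
  G <- gram_cube(subjects)
  path <- cpp_network_path(G, lambda, tol * (Tn - 1), as.integer(max_iter))
  rawc <- path$raw[[1]]
  networks <- lapply(seq_along(subjects), function(i) {
    finalize_connectivity(rawc[, , i], "GSR", lambda,
                          subjects[[i]]$subject_id, subjects[[i]]$roi_labels)
  })
  out <- list(networks = networks, support = path$support[[1]],
              lambda = lambda)
  if (keep_raw) {
    out$raw <- lapply(seq_along(subjects), function(i) rawc[, , i])
  }
  class(out) <- "gsr_network_set"
  out
}

#' @export
print.gsr_network_set <- function(x, ...) {
  cat(sprintf("<gsr_network_set> %d subjects, lambda = %.4g, %d support rows\n",
              length(x$networks), x$lambda,
              sum(lengths(x$support) > 0)))
  invisible(x)
}

#' Encode a held-out subject on a learned group support
#'
#' A subject that did not participate in group support learning (the test
#' subject of a cross-validation fold) is encoded by a per-ROI regression
#' restricted to the predictor support learned from the training subjects;
#' coefficients outside the support are zero.  With `shrink_lambda = 0` the
#' restricted fit is unregularized least squares (ridge fallback for
#' rank-deficient systems); with `shrink_lambda > 0` it is an l1 fit at that
#' penalty.  The cross-validation engine encodes at
#' `lambda / sqrt(N_train)`, the single-subject equivalent of the group
#' penalty (a group problem over N identical subjects reduces to the
#' single-subject problem at `lambda / sqrt(N)`), so held-out features carry
#' the same shrinkage as the training features they are compared with.
#' Fisher z and bidirectional averaging then proceed as in
#' [gsr_network_set()].
#'
#' @param support per-ROI predictor index sets (from [gsr_network_set()]).
#' @param ts the held-out subject's [roi_timeseries].
#' @param lambda the lambda tag for the resulting matrix (bookkeeping only).
#' @param shrink_lambda l1 penalty for the restricted fit (0 = plain least
#'   squares).
#' @param ridge_rel relative ridge constant for the least-squares fallback.
#' @return A [connectivity_matrix] with method `"GSR"`; attribute `n_ridge`
#'   counts ridge fallbacks.
#' @export
encode_new_subject <- function(support, ts, lambda = NA_real_,
                               shrink_lambda = 0, ridge_rel = 1e-6) {
  ts <- ensure_conditioned(ts)
  R <- ncol(ts$data)
  if (length(support) != R) {
    stop("encode_new_subject: support must have one index set per ROI")
  }
  enc <- cpp_encode_from_gram(subject_gram(ts), support, shrink_lambda,
                              ridge_rel, 1e-8 * (nrow(ts$data) - 1))
  cm <- finalize_connectivity(enc$raw, "GSR", lambda, ts$subject_id,
                              ts$roi_labels)
  attr(cm, "n_ridge") <- enc$n_ridge
  cm
}
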