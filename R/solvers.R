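#' l1-penalized node-wise regression solver
#'
#' Minimizes `0.5 * ||y - X w||^2 + lambda * ||w||_1` by cyclic coordinate
#' descent with residual updates.  Convergence is certified by the KKT
#' conditions of the problem; the returned solution always passes
#' [check_kkt_l1()] at the requested tolerance.
#'
#' @param X design matrix (columns standardized; see
#'   [condition_timeseries()] for the network use).
#' @param y response vector (demeaned).
#' @param lambda penalty weight, `lambda >= 0`.
#' @param tol KKT tolerance.
#' @param max_iter maximum coordinate-descent sweeps.
#' @return Numeric coefficient vector of length `ncol(X)`.
#' @export
solve_l1 <- function(X, y, lambda, tol = 1e-8, max_iter = 10000L) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), lambda >= 0)
  fit <- cpp_lasso_path(X, as.numeric(y), lambda, tol, as.integer(max_iter))
  if (fit$kkt[1] > tol) {
    stop(sprintf("solve_l1: no convergence in %d sweeps (KKT violation %.3e)",
                 max_iter, fit$kkt[1]))
  }
  drop(fit$coef)
}

#' KKT optimality certificate for the l1 problem
#'
#' Verifies `|x_j'(y - Xw) - lambda * sign(w_j)| <= tol` for active
#' coefficients and `|x_j'(y - Xw)| <= lambda + tol` for zero coefficients.
#'
#' @inheritParams solve_l1
#' @param w candidate solution.
#' @return list with `pass` (logical) and `worst` (largest violation).
#' @export
check_kkt_l1 <- function(X, y, w, lambda, tol = 1e-6) {
  X <- as.matrix(X)
  g <- drop(crossprod(X, y - X %*% w))
  viol <- ifelse(w != 0, abs(g - lambda * sign(w)), pmax(abs(g) - lambda, 0))
  list(pass = all(viol <= tol), worst = max(viol))
}

#' Smallest all-zero penalty for the l1 problem
#'
#' @inheritParams solve_l1
#' @return `max_j |x_j' y|`: at any `lambda` at or above this value the l1
#'   solution is exactly zero.
#' @export
lambda_max_l1 <- function(X, y) {
  max(abs(drop(crossprod(as.matrix(X), y))))
}

as_problem_lists <- function(X_list, y_list) {
  if (is.matrix(X_list)) X_list <- list(X_list)
  if (is.numeric(y_list)) y_list <- list(y_list)
  stopifnot(length(X_list) == length(y_list), length(X_list) >= 1)
  p <- unique(vapply(X_list, ncol, integer(1)))
  if (length(p) != 1) stop("all designs must share the same predictor count")
  for (i in seq_along(X_list)) {
    if (nrow(X_list[[i]]) != length(y_list[[i]])) {
      stop("design/target dimension mismatch for subject ", i)
    }
  }
  list(X = lapply(X_list, as.matrix), y = lapply(y_list, as.numeric), p = p)
}

group_gram_cube <- function(X_list, y_list) {
  p <- ncol(X_list[[1]])
  N <- length(X_list)
  G <- array(0, dim = c(p + 1, p + 1, N))
  for (i in seq_len(N)) {
    Zi <- cbind(X_list[[i]], y_list[[i]])
    G[, , i] <- crossprod(Zi)
  }
  G
}

#' Multi-subject l2,1-penalized (group) regression solver
#'
#' Minimizes `sum_i 0.5 * ||y_i - X_i w_i||^2 + lambda * sum_j ||W_j.||_2`
#' over the coefficient matrix `W` whose column `i` belongs to subject `i`
#' and whose row `j` collects predictor `j` across subjects.  The l2,1
#' penalty zeroes whole rows, so the nonzero predictor support is identical
#' across subjects by construction.  Solved by row-wise block coordinate
#' descent with block soft-thresholding (exact closed-form row updates when
#' all designs are column-standardized, which gives equal curvatures).
#'
#' @param X_list list of per-subject design matrices (same column count).
#' @param y_list list of per-subject response vectors.
#' @param lambda group penalty weight, `lambda >= 0`.
#' @param tol KKT tolerance.
#' @param max_iter maximum block-coordinate sweeps.
#' @return `p x N` coefficient matrix.
#' @export
solve_group_l21 <- function(X_list, y_list, lambda, tol = 1e-8,
                            max_iter = 10000L) {
  pr <- as_problem_lists(X_list, y_list)
  G <- group_gram_cube(pr$X, pr$y)
  fit <- cpp_group_cd(G, target = pr$p, lambdas = lambda, tol = tol,
                      max_iter = as.integer(max_iter))
  if (fit$kkt[1] > tol) {
    stop(sprintf("solve_group_l21: no convergence in %d sweeps (KKT violation %.3e)",
                 max_iter, fit$kkt[1]))
  }
  W <- fit$coef[[1]]
  W[seq_len(pr$p), , drop = FALSE]
}

#' KKT optimality certificate for the l2,1 problem
#'
#' With `g_j` stacking `x_{i,j}'(y_i - X_i w_i)` over subjects, verifies
#' `||g_j||_2 <= lambda + tol` for zero rows and
#' `||g_j - lambda * W_j. / ||W_j.||_2 || <= tol` for nonzero rows.
#'
#' @inheritParams solve_group_l21
#' @param W candidate `p x N` solution.
#' @return list with `pass` and `worst`.
#' @export
check_kkt_group_l21 <- function(X_list, y_list, W, lambda, tol = 1e-6) {
  pr <- as_problem_lists(X_list, y_list)
  N <- length(pr$X)
  Gmat <- vapply(seq_len(N), function(i) {
    drop(crossprod(pr$X[[i]], pr$y[[i]] - pr$X[[i]] %*% W[, i]))
  }, numeric(pr$p))
  Gmat <- matrix(Gmat, nrow = pr$p)
  rown <- sqrt(rowSums(W^2))
  viol <- numeric(pr$p)
  for (j in seq_len(pr$p)) {
    if (rown[j] > 0) {
      viol[j] <- sqrt(sum((Gmat[j, ] - lambda * W[j, ] / rown[j])^2))
    } else {
      viol[j] <- max(sqrt(sum(Gmat[j, ]^2)) - lambda, 0)
    }
  }
  list(pass = all(viol <= tol), worst = max(viol))
}

#' Smallest all-zero penalty for the l2,1 problem
#'
#' @inheritParams solve_group_l21
#' @return `max_j ||(x_{1,j}'y_1, ..., x_{N,j}'y_N)||_2`: at any `lambda` at
#'   or above this value the group solution is exactly zero.
#' @export
lambda_max_gsr <- function(X_list, y_list) {
  pr <- as_problem_lists(X_list, y_list)
  Gmat <- vapply(seq_along(pr$X), function(i) {
    drop(crossprod(pr$X[[i]], pr$y[[i]]))
  }, numeric(pr$p))
  Gmat <- matrix(Gmat, nrow = pr$p)
  max(sqrt(rowSums(Gmat^2)))
}
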