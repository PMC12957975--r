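#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the second-order structure that sparse network
#' construction assumes: each subject's ROI signal is multivariate Gaussian
#' with a sparse precision-matrix support shared across the cohort, a
#' designated subset of edges whose partial-correlation strength differs
#' between the two groups, subject-level jitter of edge weights, and white
#' observation noise.
#'
#' Defaults mirror a resting-state ROI extraction (116 regions, 230 time
#' points) with moderate cohort sizes.  `effect_delta` is a shift in
#' partial-correlation magnitude on effect edges; `subject_jitter_sd`
#' perturbs precision entries per subject on the shared support.
#'
#' @param n_regions number of ROIs (R >= 4).
#' @param n_timepoints time points per subject (T > R so node-wise
#'   regressions are overdetermined).
#' @param n_per_group subjects per group.
#' @param support_density fraction of off-diagonal edges present in the
#'   shared precision support (0 < density < 1).
#' @param n_effect_edges number of support edges whose strength differs
#'   between groups.
#' @param effect_delta between-group shift in partial-correlation magnitude
#'   on effect edges (dimensionless).
#' @param subject_jitter_sd standard deviation of per-subject symmetric
#'   jitter added to precision entries on the support (dimensionless).
#' @param noise_sd standard deviation of additive white observation noise.
#' @param seed integer RNG seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_regions = 116, n_timepoints = 230,
                             n_per_group = 20, support_density = 0.1,
                             n_effect_edges = 10, effect_delta = 0.15,
                             subject_jitter_sd = 0.2, noise_sd = 1.0,
                             seed = 1) {
  cfg <- list(n_regions = as.integer(n_regions),
              n_timepoints = as.integer(n_timepoints),
              n_per_group = as.integer(n_per_group),
              support_density = support_density,
              n_effect_edges = as.integer(n_effect_edges),
              effect_delta = effect_delta,
              subject_jitter_sd = subject_jitter_sd,
              noise_sd = noise_sd, seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_regions < 4) stop("synthetic_config: n_regions must be >= 4")
  if (cfg$n_timepoints <= cfg$n_regions) {
    stop("synthetic_config: n_timepoints must exceed n_regions")
  }
  if (cfg$n_per_group < 1) stop("synthetic_config: n_per_group must be >= 1")
  if (cfg$support_density <= 0 || cfg$support_density >= 1) {
    stop("synthetic_config: support_density must be in (0, 1)")
  }
  n_pairs <- cfg$n_regions * (cfg$n_regions - 1) / 2
  n_support <- max(1L, round(cfg$support_density * n_pairs))
  if (cfg$n_effect_edges > n_support) {
    stop("synthetic_config: n_effect_edges exceeds the number of support edges")
  }
  if (cfg$n_effect_edges < 0 || cfg$effect_delta < 0 ||
      cfg$subject_jitter_sd < 0 || cfg$noise_sd < 0) {
    stop("synthetic_config: negative parameter")
  }
  invisible(cfg)
}

# Diagonal loading: add eps * I, doubling eps until the Cholesky
# factorization succeeds (cap 10 attempts).  Returns the loaded matrix and
# its Cholesky factor.
load_to_pd <- function(omega, context = "precision matrix") {
  ch <- tryCatch(chol(omega), error = function(e) NULL)
  if (!is.null(ch)) return(list(omega = omega, chol = ch, eps = 0))
  eps <- 0.05
  for (k in seq_len(10)) {
    cand <- omega + eps * diag(nrow(omega))
    ch <- tryCatch(chol(cand), error = function(e) NULL)
    if (!is.null(ch)) return(list(omega = cand, chol = ch, eps = eps))
    eps <- eps * 2
  }
  stop(sprintf("generation failure: %s not positive definite after maximum diagonal loading", context))
}

# All unordered ROI pairs (i < j), row-major order.
all_pairs <- function(R) {
  idx <- which(lower.tri(matrix(0, R, R)), arr.ind = TRUE)
  cbind(i = idx[, "col"], j = idx[, "row"])[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
}

#' Generate a synthetic two-group cohort with known network structure
#'
#' Draws each subject's `T x R` signal as `T` independent samples from a
#' zero-mean multivariate Gaussian.  Both groups share a sparse precision
#' support; effect edges carry a partial-correlation magnitude shifted by
#' `effect_delta` in group B.  Each subject's precision adds symmetric
#' Gaussian jitter on the support, re-symmetrized and made positive definite
#' by diagonal loading; white noise of sd `noise_sd` is added to the signal.
#' Group A subjects are labeled -1, group B +1.
#'
#' @param config a [synthetic_config].
#' @return A list-like [cohort] whose `ground_truth` element holds
#'   `support_edges` and `effect_edges` (1-based `i < j` pairs) and the two
#'   group-level precision matrices.
#' @export
generate_cohort <- function(config) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  R <- config$n_regions
  Tn <- config$n_timepoints
  pairs <- all_pairs(R)
  n_pairs <- nrow(pairs)
  n_support <- max(1L, round(config$support_density * n_pairs))
  sup_idx <- sort(sample.int(n_pairs, n_support))
  support <- pairs[sup_idx, , drop = FALSE]
  eff_rows <- if (config$n_effect_edges > 0) {
    sort(sample.int(n_support, config$n_effect_edges))
  } else integer(0)

  # base partial-correlation strengths on the support
  mag <- runif(n_support, 0.15, 0.35)
  sgn <- sample(c(-1, 1), n_support, replace = TRUE)
  rho_a <- sgn * mag
  rho_b <- rho_a
  if (length(eff_rows) > 0) {
    rho_b[eff_rows] <- sgn[eff_rows] * pmin(mag[eff_rows] + config$effect_delta, 0.8)
  }

  build_omega <- function(rho) {
    om <- diag(R)
    om[cbind(support[, 1], support[, 2])] <- -rho
    om[cbind(support[, 2], support[, 1])] <- -rho
    om
  }
  om_a <- build_omega(rho_a)
  om_b <- build_omega(rho_b)
  # common loading keeps the two groups on the same diagonal scale
  eps_a <- load_to_pd(om_a, "group A precision")$eps
  eps_b <- load_to_pd(om_b, "group B precision")$eps
  eps <- max(eps_a, eps_b)
  om_a <- om_a + eps * diag(R)
  om_b <- om_b + eps * diag(R)

  n <- config$n_per_group
  subjects <- vector("list", 2L * n)
  labels <- rep(c(-1L, 1L), each = n)
  roi_labels <- sprintf("roi_%d", seq_len(R))
  for (s in seq_len(2L * n)) {
    om_g <- if (labels[s] < 0) om_a else om_b
    om_s <- om_g
    if (config$subject_jitter_sd > 0) {
      jit <- rnorm(n_support, sd = config$subject_jitter_sd)
      om_s[cbind(support[, 1], support[, 2])] <-
        om_s[cbind(support[, 1], support[, 2])] + jit
      om_s[cbind(support[, 2], support[, 1])] <-
        om_s[cbind(support[, 2], support[, 1])] + jit
    }
    loaded <- load_to_pd(om_s, sprintf("subject %d precision", s))
    z <- matrix(rnorm(Tn * R), Tn, R)
    x <- t(backsolve(loaded$chol, t(z)))
    if (config$noise_sd > 0) x <- x + config$noise_sd * matrix(rnorm(Tn * R), Tn, R)
    subjects[[s]] <- roi_timeseries(
      x, subject_id = sprintf("sub%03d", s), roi_labels = roi_labels
    )
  }
  gt <- structure(
    list(support_edges = unname(support), effect_edges = unname(support[eff_rows, , drop = FALSE]),
         precision_a = om_a, precision_b = om_b, loading = eps),
    class = "ground_truth"
  )
  cohort(subjects, labels, ground_truth = gt)
}

#' Generate a null cohort with no group signal
#'
#' All subjects are i.i.d. standard Gaussian white noise; labels split the
#' cohort into two arbitrary halves.  Used for leakage / calibration checks:
#' any classifier evaluated without leakage must perform at chance.
#'
#' @param n_regions,n_timepoints,n_per_group positive counts.
#' @param seed integer RNG seed.
#' @return A [cohort] with no ground truth.
#' @export
generate_null_cohort <- function(n_regions, n_timepoints, n_per_group, seed = 1) {
  if (n_regions < 2 || n_timepoints < 3 || n_per_group < 1) {
    stop("generate_null_cohort: counts must be positive (n_per_group >= 1, n_timepoints >= 3)")
  }
  set.seed(seed)
  n <- 2L * as.integer(n_per_group)
  roi_labels <- sprintf("roi_%d", seq_len(n_regions))
  subjects <- lapply(seq_len(n), function(s) {
    roi_timeseries(matrix(rnorm(n_timepoints * n_regions), n_timepoints),
                   subject_id = sprintf("sub%03d", s), roi_labels = roi_labels)
  })
  cohort(subjects, rep(c(-1L, 1L), each = n_per_group))
}

#' Regression fixture with a closed-form l1 solution
#'
#' Builds a standardized design with a known sparse coefficient vector and a
#' noisy response.  With `orthonormal = TRUE` the columns are orthonormalized
#' so that the lasso solution has the elementwise soft-threshold closed form
#' `soft(X'y, lambda)` - the independent oracle used to certify the solver.
#'
#' @param n_predictors,n_samples dimensions (`n_samples >= n_predictors`).
#' @param seed integer RNG seed.
#' @param orthonormal orthonormalize the design columns.
#' @param noise_sd response noise level.
#' @return list with `X`, `y`, `beta` (generating coefficients), and
#'   `orthonormal` flag.
#' @export
make_solver_fixture <- function(n_predictors, n_samples, seed = 1,
                                orthonormal = TRUE, noise_sd = 0.1) {
  if (n_samples < n_predictors) {
    stop("make_solver_fixture: n_samples must be >= n_predictors")
  }
  set.seed(seed)
  X <- matrix(rnorm(n_samples * n_predictors), n_samples)
  X <- scale(X, center = TRUE, scale = FALSE)
  if (orthonormal) {
    X <- qr.Q(qr(X))[, seq_len(n_predictors), drop = FALSE]
  } else {
    X <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  }
  k <- max(1L, ceiling(n_predictors / 3))
  beta <- numeric(n_predictors)
  beta[seq_len(k)] <- sample(c(-1, 1), k, TRUE) * runif(k, 0.5, 1.5)
  y <- drop(X %*% beta) + noise_sd * rnorm(n_samples)
  y <- y - mean(y)
  list(X = unname(X), y = y, beta = beta, orthonormal = orthonormal)
}
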