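# Shared fixtures: everything is generated in code under fixed seeds.

small_cohort <- function(seed = 1, R = 10, Tn = 60, n = 5, ...) {
  n_support <- max(1, round(0.2 * R * (R - 1) / 2))
  args <- list(n_regions = R, n_timepoints = Tn, n_per_group = n,
               support_density = 0.2, n_effect_edges = min(4, n_support),
               seed = seed)
  generate_cohort(do.call(synthetic_config, utils::modifyList(args, list(...))))
}

# A cohort with a strong, noiseless group difference: appends a synthetic
# "lesion" by shifting one ROI pair's coupling far apart between groups.
separable_cohort <- function(seed = 2, R = 8, Tn = 80, n = 5) {
  generate_cohort(synthetic_config(
    n_regions = R, n_timepoints = Tn, n_per_group = n,
    support_density = 0.2, n_effect_edges = 6, effect_delta = 0.6,
    subject_jitter_sd = 0, noise_sd = 0, seed = seed
  ))
}

random_l1_problem <- function(seed, n = 40, p = 10) {
  set.seed(seed)
  X <- scale(matrix(rnorm(n * p), n))
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  beta <- numeric(p)
  beta[seq_len(ceiling(p / 3))] <- rnorm(ceiling(p / 3), sd = 1.5)
  y <- drop(X %*% beta) + rnorm(n, sd = 0.5)
  y <- y - mean(y)
  list(X = unclass(X), y = y)
}

random_group_problem <- function(seed, N = 3, n = 30, p = 8) {
  set.seed(seed)
  Xs <- lapply(seq_len(N), function(i) {
    X <- scale(matrix(rnorm(n * p), n))
    attr(X, "scaled:center") <- NULL
    attr(X, "scaled:scale") <- NULL
    unclass(X)
  })
  beta <- numeric(p)
  beta[1:3] <- c(1.2, -0.8, 0.5)
  ys <- lapply(Xs, function(X) {
    y <- drop(X %*% (beta + rnorm(p, sd = 0.1))) + rnorm(n, sd = 0.5)
    y - mean(y)
  })
  list(X = Xs, y = ys)
}

# empirical partial correlations from pooled samples (brute force:
# invert the pooled covariance and normalize)
empirical_partial_cor <- function(data_list) {
  pooled <- do.call(rbind, lapply(data_list, scale))
  om <- solve(cov(pooled))
  d <- sqrt(diag(om))
  -om / outer(d, d)
}
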