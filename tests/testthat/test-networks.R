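test_that("conditioning standardizes, errors on constant ROIs, and is idempotent", {
  ts <- roi_timeseries(cbind(a = c(1, 2, 3), b = c(2, 1, 3)))
  cd <- condition_timeseries(ts)
  expect_equal(unname(colMeans(cd$data)), c(0, 0))
  expect_equal(unname(apply(cd$data, 2, sd)), c(1, 1))
  cd2 <- condition_timeseries(cd)
  expect_lt(max(abs(cd2$data - cd$data)), 1e-12)
  bad <- roi_timeseries(cbind(a = c(1, 2, 3), flat = c(5, 5, 5)))
  expect_error(condition_timeseries(bad), "flat")
})

test_that("pearson network matches hand-computed correlations and clips self-similarity", {
  # x = (1,2,3), y = (1,2,4): r = 3 / sqrt(2 * 14/3)
  ts <- roi_timeseries(cbind(x = c(1, 2, 3), y = c(1, 2, 4)))
  net <- pearson_network(ts)
  r <- 3 / sqrt(2 * 14 / 3)
  expect_equal(net[1, 2], atanh(r), tolerance = 1e-12)
  expect_identical(unname(diag(unclass(net))), c(0, 0))

  # orthogonal signals: z = 0
  ts0 <- roi_timeseries(cbind(x = c(1, -1, 1, -1), y = c(1, 1, -1, -1)))
  expect_equal(pearson_network(ts0)[1, 2], 0)

  # duplicated ROI: r = 1 clipped to 1 - 1e-7 before atanh
  tsd <- roi_timeseries(cbind(a = c(1, 2, 3, 5), b = c(1, 2, 3, 5) * 2,
                              c = c(0, 1, 0, 2)))
  netd <- pearson_network(tsd)
  expect_equal(netd[1, 2], atanh(1 - 1e-7))
})

test_that("connectivity matrix invariants are enforced on construction", {
  m <- matrix(c(0, 1, 1, 0), 2)
  expect_s3_class(connectivity_matrix(m, "PC"), "connectivity_matrix")
  expect_error(connectivity_matrix(matrix(c(0, 1, 2, 0), 2), "PC"),
               "symmetric")
  expect_error(connectivity_matrix(matrix(c(1, 1, 1, 0), 2), "PC"),
               "diagonal")
  m[1, 2] <- m[2, 1] <- Inf
  expect_error(connectivity_matrix(m, "PC"), "finite")
})

test_that("sr network: lambda_max endpoint, one-sided symmetrization, sparser than PC", {
  co <- small_cohort(seed = 4, R = 8, Tn = 60)
  ts <- condition_timeseries(co$subjects[[1]])
  lmax <- lambda_max_sr(ts)
  z <- sr_network(ts, 1.001 * lmax)
  expect_identical(sum(unclass(z) != 0), 0L)
  net <- sr_network(ts, 0.5 * lmax)
  pc <- pearson_network(ts)
  expect_lt(sum(unclass(net) != 0), sum(unclass(pc) != 0))

  # one-sided raw weight w symmetrizes to atanh(w)/2
  raw <- matrix(0, 4, 4)
  raw[1, 2] <- 0.5
  fin <- gsrnet:::cpp_finalize_network(raw)
  expect_equal(fin$matrix[1, 2], atanh(0.5) / 2)
  expect_equal(fin$matrix[2, 1], atanh(0.5) / 2)
  # weights at or beyond 1 are clipped, not NaN
  raw[3, 4] <- 1.2
  fin2 <- gsrnet:::cpp_finalize_network(raw)
  expect_true(is.finite(fin2$matrix[3, 4]))
  expect_equal(fin2$matrix[3, 4], atanh(1 - 1e-7) / 2)
  expect_identical(fin2$n_clipped, 1L)
})

test_that("sr network nonzero pattern matches a glmnet-solved node-wise lasso", {
  skip_if_not_installed("glmnet")
  co <- small_cohort(seed = 6, R = 6, Tn = 80)
  ts <- condition_timeseries(co$subjects[[1]])
  lmax <- lambda_max_sr(ts)
  lam <- 0.2 * lmax
  net <- sr_network(ts, lam)
  Tn <- nrow(ts$data)
  raw_oracle <- matrix(0, 6, 6)
  for (r in 1:6) {
    g <- glmnet::glmnet(ts$data[, -r], ts$data[, r], lambda = lam / Tn,
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-14)
    raw_oracle[r, -r] <- as.numeric(g$beta)
  }
  fin <- gsrnet:::cpp_finalize_network(raw_oracle)
  expect_equal(unclass(net) != 0, fin$matrix != 0, ignore_attr = TRUE)
  expect_equal(unclass(net), fin$matrix, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("gsr network set: shared support, single-subject reduction, zero endpoint", {
  co <- small_cohort(seed = 8, R = 12, Tn = 80, n = 5)
  subjects <- lapply(co$subjects, condition_timeseries)
  lmax <- lambda_max_gsr_cohort(subjects)
  gs <- gsr_network_set(subjects, 0.3 * lmax, keep_raw = TRUE)
  # pre-symmetrization row support identical across subjects
  sup <- lapply(gs$raw, function(raw) raw != 0)
  for (i in 2:length(sup)) expect_identical(sup[[i]], sup[[1]])
  # above lambda_max: all matrices exactly zero
  gz <- gsr_network_set(subjects, 1.01 * lmax)
  expect_true(all(vapply(gz$networks, function(m) all(unclass(m) == 0),
                         logical(1))))
  # single-subject cohort reduces to the SR network at the same lambda
  one <- subjects[[3]]
  lam1 <- 0.4 * lambda_max_sr(one)
  g1 <- gsr_network_set(list(one), lam1)
  s1 <- sr_network(one, lam1)
  expect_equal(unclass(g1$networks[[1]]), unclass(s1), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("encoding a held-out subject respects the learned support", {
  co <- small_cohort(seed = 10, R = 10, Tn = 100, n = 5)
  subjects <- lapply(co$subjects, condition_timeseries)
  train <- subjects[1:9]
  test <- subjects[[10]]
  lmax <- lambda_max_gsr_cohort(train)
  gs <- gsr_network_set(train, 0.3 * lmax)
  enc <- encode_new_subject(gs$support, test)
  # encoded edges only where the learned support allows them
  allowed <- matrix(FALSE, 10, 10)
  for (r in 1:10) allowed[r, gs$support[[r]]] <- TRUE
  allowed <- allowed | t(allowed)
  expect_true(all(unclass(enc)[!allowed] == 0))
  # empty support for every ROI -> zero matrix
  empty <- replicate(10, integer(0), simplify = FALSE)
  enc0 <- encode_new_subject(empty, test)
  expect_true(all(unclass(enc0) == 0))
  # full support on one ROI -> restricted fit equals OLS
  full <- c(list(2:10), replicate(9, integer(0), simplify = FALSE))
  encf <- encode_new_subject(full, test)
  ols <- drop(solve(crossprod(test$data[, -1]),
                    crossprod(test$data[, -1], test$data[, 1])))
  raw <- gsrnet:::cpp_encode_from_gram(crossprod(test$data), full, 0, 1e-6,
                                       1e-10)$raw
  expect_equal(raw[1, -1], ols, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("encoded weights correlate positively with in-group GSR weights on the true support", {
  cors <- sapply(1:10, function(seed) {
    co <- small_cohort(seed = seed, R = 10, Tn = 120, n = 5,
                       subject_jitter_sd = 0.05, noise_sd = 0.2)
    subjects <- lapply(co$subjects, condition_timeseries)
    lmax_tr <- lambda_max_gsr_cohort(subjects[-10])
    gs <- gsr_network_set(subjects[-10], 0.3 * lmax_tr)
    enc <- encode_new_subject(gs$support, subjects[[10]])
    lmax_all <- lambda_max_gsr_cohort(subjects)
    full <- gsr_network_set(subjects, 0.3 * lmax_all)
    ing <- full$networks[[10]]
    sup <- co$ground_truth$support_edges
    fe <- unclass(enc)[sup]
    fi <- unclass(ing)[sup]
    keep <- fe != 0 | fi != 0
    if (sum(keep) < 3) return(NA)
    cor(fe[keep], fi[keep])
  })
  expect_gt(median(cors, na.rm = TRUE), 0.5)
  expect_true(all(cors > 0, na.rm = TRUE))
})
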