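test_that("upper-triangle vectorization is the documented bijection", {
  map3 <- upper_triangle_map(3)
  expect_equal(map3$roi_i, c(1, 1, 2))
  expect_equal(map3$roi_j, c(2, 3, 3))
  expect_identical(nrow(upper_triangle_map(116)), 6670L)

  set.seed(1)
  m <- matrix(rnorm(25), 5)
  m <- m + t(m)
  diag(m) <- 0
  f <- vectorize_upper_triangle(m)
  expect_identical(length(f), 10L)
  map <- upper_triangle_map(5)
  for (k in seq_len(10)) {
    expect_identical(f[k], m[map$roi_i[k], map$roi_j[k]])
  }
  expect_identical(matrix_from_features(f, 5), m)
  expect_error(vectorize_upper_triangle(matrix(rnorm(9), 3)), "symmetric")
})

test_that("lasso selection: empty above lambda_max, finds a perfect feature, no sign-flipped duplicates", {
  set.seed(42)
  n <- 24
  labels <- rep(c(-1, 1), n / 2)
  noise <- matrix(rnorm(n * 30), n)
  feats <- cbind(labels, noise)  # feature 1 is the label itself
  expect_identical(lasso_select(feats, labels, lambda = 2), integer(0))

  hits <- sapply(1:20, function(seed) {
    set.seed(seed)
    f <- cbind(labels, matrix(rnorm(n * 30), n))
    1 %in% lasso_select(f, labels, lambda = 0.05)
  })
  expect_gte(sum(hits), 19)

  # duplicated columns: lasso never selects both copies with opposite signs
  for (seed in 1:10) {
    set.seed(seed)
    f <- matrix(rnorm(n * 10), n)
    f <- cbind(f, f[, 1])  # column 11 duplicates column 1
    Fs <- scale(f)
    yc <- labels - mean(labels)
    coef <- gsrnet:::cpp_lasso_path(Fs, yc, 0.05 * n, 1e-8 * n, 5000)$coef
    expect_gte(coef[1] * coef[11], 0)
  }
})

test_that("metrics follow their defining ratios and flag undefined denominators", {
  m <- compute_metrics(c(TP = 1, FP = 0, FN = 0, TN = 1))
  expect_equal(unlist(m[c("ACC", "SEN", "SPE")]), c(ACC = 1, SEN = 1, SPE = 1))
  m2 <- compute_metrics(c(TP = 19, FN = 1, TN = 10, FP = 10))
  expect_equal(m2$SEN, 0.95)
  expect_equal(m2$SPE, 0.50)
  expect_equal(m2$ACC, 0.725)
  m3 <- compute_metrics(c(TP = 0, FN = 0, TN = 5, FP = 5))
  expect_true(is.na(m3$SEN))
  expect_identical(m3$undefined, "SEN")
  expect_error(compute_metrics(c(TP = 1, FP = 1)), "TP, FP, FN, TN")
})

test_that("rank AUC equals brute-force pairwise concordance, with ties at 1/2", {
  auc_brute <- function(scores, labels) {
    pos <- scores[labels == 1]
    neg <- scores[labels == -1]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, -1, 1, -1))$auc, 0.75)
  expect_equal(roc_auc(c(3, 2, 1), c(1, 1, -1))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(1, -1), 5))$auc, 0.5)
  set.seed(7)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    labels <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    expect_equal(roc_auc(scores, labels)$auc, auc_brute(scores, labels))
  }
})

test_that("rank AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(3)
  labels <- rep(c(-1, 1), 15)
  scores <- rnorm(30) + 0.8 * labels
  expect_equal(roc_auc(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<", levels = c(-1, 1)))))
})

test_that("nested LOOCV is perfect on a separable cohort and structurally sound", {
  co <- separable_cohort()
  cv <- nested_loocv(co, "pc")
  expect_equal(cv$metrics$ACC, 1)
  expect_equal(cv$metrics$AUC, 1)
  # structure: N folds, N-1 inner classifiers each, votes consistent
  expect_identical(length(cv$folds), length(co$subjects))
  for (f in cv$folds) {
    expect_identical(length(f$votes), length(co$subjects) - 1L)
    expect_equal(f$vote_fraction, mean(f$votes == 1))
    expect_equal(f$final_label, ifelse(f$vote_fraction >= 0.5, 1, -1))
  }
  # recomputing the metrics from stored fold results reproduces them exactly
  preds <- vapply(cv$folds, function(f) f$final_label, numeric(1))
  truth <- vapply(cv$folds, function(f) f$truth, numeric(1))
  cnt <- c(TP = sum(truth == 1 & preds == 1), FP = sum(truth == -1 & preds == 1),
           FN = sum(truth == 1 & preds == -1), TN = sum(truth == -1 & preds == -1))
  expect_identical(unname(cnt), unname(cv$counts))
  m <- compute_metrics(cnt)
  expect_equal(m$ACC, cv$metrics$ACC)
  expect_identical(sum(cnt), length(co$subjects))
})

test_that("subject order in the cohort does not change per-subject decisions", {
  co <- small_cohort(seed = 13, R = 8, Tn = 60, n = 4,
                     effect_delta = 0.3)
  cv1 <- nested_loocv(co, "pc")
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  co2 <- cohort(co$subjects[perm], co$labels[perm])
  cv2 <- nested_loocv(co2, "pc")
  expect_identical(cv1$final_labels, cv2$final_labels)
  expect_identical(cv1$vote_fractions, cv2$vote_fractions)
  # and gsr likewise (group solves see permuted Gram stacks)
  cg1 <- nested_loocv(co, "gsr", net_grid = c(0.2, 0.4))
  cg2 <- nested_loocv(co2, "gsr", net_grid = c(0.2, 0.4))
  expect_identical(cg1$final_labels, cg2$final_labels)
})

test_that("nested LOOCV validates its inputs", {
  co <- small_cohort(seed = 1, R = 6, Tn = 30, n = 2)
  expect_error(nested_loocv(co, "pc"), "at least 6|at least 3")
  co2 <- small_cohort(seed = 1, R = 6, Tn = 30, n = 4)
  expect_error(nested_loocv(co2, "sr", net_grid = numeric(0)), "net_grid")
  expect_error(nested_loocv(co2, "pc", lasso_grid = -1), "lasso_grid")
})
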