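fake_fold <- function(inner) structure(list(inner = inner), class = "fold_result")
fake_inner <- function(selected, w) {
  list(selected = selected, svm_w = w, empty_selection = length(selected) == 0)
}

test_that("aggregation arithmetic: frequencies and mean weights", {
  # one classifier selecting one connection with weight 0.7
  rep1 <- aggregate_folds(list(fake_fold(list(fake_inner(1L, 0.7)))),
                          n_regions = 4)
  expect_identical(nrow(rep1), 1L)
  expect_equal(rep1$frequency, 1)
  expect_equal(rep1$mean_weight, 0.7)
  expect_equal(rep1$roi_i, 1)
  expect_equal(rep1$roi_j, 2)

  # connection 3 selected by 5 of 10 classifiers, weights summing to 2.0
  inner <- c(
    lapply(c(0.1, 0.3, 0.5, 0.7, 0.4), function(w) fake_inner(3L, w)),
    replicate(5, fake_inner(integer(0), numeric(0)), simplify = FALSE)
  )
  rep2 <- aggregate_folds(list(fake_fold(inner)), n_regions = 4)
  expect_equal(rep2$frequency, 0.5)
  expect_equal(rep2$mean_weight, 0.4)
  expect_identical(attr(rep2, "total_classifiers"), 10L)
})

test_that("selection counts are conserved between folds and report", {
  co <- separable_cohort()
  cv <- nested_loocv(co, "pc")
  rep <- aggregate_folds(cv)
  total_sel <- sum(vapply(cv$folds, function(f) {
    sum(vapply(f$inner, function(i) length(i$selected), integer(1)))
  }, integer(1)))
  expect_identical(sum(rep$n_selected), total_sel)
  expect_true(all(rep$frequency > 0 & rep$frequency <= 1))
})

test_that("effect edges dominate the discriminative ranking on synthetic cohorts", {
  ranks <- sapply(1:10, function(seed) {
    co <- generate_cohort(synthetic_config(
      n_regions = 10, n_timepoints = 80, n_per_group = 5,
      support_density = 0.2, n_effect_edges = 3, effect_delta = 0.5,
      subject_jitter_sd = 0.02, noise_sd = 0.1, seed = seed
    ))
    cv <- nested_loocv(co, "pc")
    rep <- aggregate_folds(cv)
    eff <- co$ground_truth$effect_edges
    effkey <- paste(eff[, 1], eff[, 2])
    repkey <- paste(rep$roi_i, rep$roi_j)
    # median rank (by frequency) of the effect edges, normalized
    pos <- match(effkey, repkey)
    pos[is.na(pos)] <- nrow(rep) + 1
    median(pos) / nrow(rep)
  })
  expect_lt(median(ranks), 0.35)
})

test_that("atlas naming matches the AAL-116 table and rejects unknown indices", {
  at <- aal116_atlas()
  expect_identical(at$name[24], "Right superior frontal gyrus, medial")
  expect_identical(at$name[112], "Vermis.6")
  expect_identical(at$name[11], "Left inferior frontal gyrus, opercular part")
  expect_identical(at$name[75], "Left lenticular nucleus, pallidum")
  expect_identical(sum(at$class == "subcortical"), 8L)
  expect_identical(sum(at$class == "cerebellar"), 26L)

  rep <- structure(
    data.frame(roi_i = c(24, 112), roi_j = c(11, 30),
               mean_weight = c(0.5, -0.2), frequency = c(0.9, 0.4),
               n_selected = c(9L, 4L)),
    class = c("discriminative_report", "data.frame"),
    total_classifiers = 10L, n_regions = 116
  )
  named <- name_connections(rep)
  expect_identical(named$connections$name_i[1],
                   "Right superior frontal gyrus, medial")
  expect_identical(named$connections$name_j[1],
                   "Left inferior frontal gyrus, opercular part")
  expect_identical(named$regions$index, c(11, 24, 30, 112))
  expect_identical(named$class_counts$cerebellar, 1L)
  bad <- rep
  bad$roi_j[1] <- 117
  expect_error(name_connections(bad), "117")
})

test_that("select_top rules: top-k, thresholds, deterministic ordering", {
  rep <- structure(
    data.frame(roi_i = c(1, 1, 2, 3), roi_j = c(2, 3, 3, 4),
               mean_weight = c(0.2, -0.9, 0.9, 0.1),
               frequency = c(0.5, 0.8, 0.8, 0.1),
               n_selected = c(5L, 8L, 8L, 1L)),
    class = c("discriminative_report", "data.frame"),
    total_classifiers = 10L, n_regions = 5
  )
  expect_identical(nrow(select_top(rep, k = 0)), 0L)
  all_sorted <- select_top(rep, k = 10)
  expect_identical(nrow(all_sorted), 4L)
  # frequency desc, then |mean weight| desc (tie at 0.8 -> equal |w|,
  # broken by index pair), then pair asc
  expect_identical(all_sorted$roi_i, c(1, 2, 1, 3))
  thr <- select_top(rep, freq_threshold = 0.5)
  expect_identical(nrow(thr), 3L)
  # 17-row cut yields a region roster equal to the union of its endpoints
  co <- separable_cohort()
  cv <- nested_loocv(co, "pc")
  full <- aggregate_folds(cv)
  k <- min(17L, nrow(full))
  top <- select_top(full, k = k)
  expect_identical(nrow(top), k)
  named <- name_connections(top, atlas = data.frame(
    index = 1:8, code = letters[1:8], name = paste("region", 1:8),
    class = rep("cortical", 8)
  ))
  expect_identical(named$regions$index,
                   sort(unique(c(top$roi_i, top$roi_j))))
})

test_that("naming after selection is independent of record order", {
  rep <- structure(
    data.frame(roi_i = c(3, 1, 2), roi_j = c(4, 2, 3),
               mean_weight = c(0.1, 0.2, -0.4),
               frequency = c(0.1, 0.5, 0.8), n_selected = c(1L, 5L, 8L)),
    class = c("discriminative_report", "data.frame"),
    total_classifiers = 10L, n_regions = 5
  )
  shuf <- rep[c(2, 3, 1), ]
  class(shuf) <- class(rep)
  attr(shuf, "total_classifiers") <- 10L
  at <- data.frame(index = 1:5, code = letters[1:5],
                   name = paste("r", 1:5), class = rep("cortical", 5))
  expect_identical(name_connections(select_top(rep, k = 2), at),
                   name_connections(select_top(shuf, k = 2), at))
})
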