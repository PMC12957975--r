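#' Classification metrics from confusion counts
#'
#' `ACC = (TP+TN)/(TP+TN+FP+FN)`, `SEN = TP/(TP+FN)`, `SPE = TN/(TN+FP)`,
#' with the patient group (+1) as the positive class.  Undefined
#' denominators yield `NA` and are flagged, never silently zero.
#'
#' @param counts named vector or list with `TP`, `FP`, `FN`, `TN`.
#' @return list with `ACC`, `SEN`, `SPE`, and `undefined` (character vector
#'   of metrics whose denominator was zero).
#' @export
compute_metrics <- function(counts) {
  counts <- as.list(counts)
  req <- c("TP", "FP", "FN", "TN")
  if (!all(req %in% names(counts))) {
    stop("compute_metrics: counts must contain TP, FP, FN, TN")
  }
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN; tn <- counts$TN
  if (any(c(tp, fp, fn, tn) < 0)) stop("compute_metrics: negative count")
  total <- tp + fp + fn + tn
  if (total <= 0) stop("compute_metrics: no evaluated subjects")
  undefined <- character(0)
  acc <- (tp + tn) / total
  if (tp + fn > 0) sen <- tp / (tp + fn) else { sen <- NA_real_; undefined <- c(undefined, "SEN") }
  if (tn + fp > 0) spe <- tn / (tn + fp) else { spe <- NA_real_; undefined <- c(undefined, "SPE") }
  list(ACC = acc, SEN = sen, SPE = spe, undefined = undefined)
}

confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  c(TP = sum(truth == 1 & pred == 1), FP = sum(truth == -1 & pred == 1),
    FN = sum(truth == 1 & pred == -1), TN = sum(truth == -1 & pred == -1))
}

#' ROC curve and AUC by rank statistics
#'
#' AUC equals the probability that a random positive subject's score exceeds
#' a random negative's, with ties contributing 1/2 (midrank formulation;
#' identical to the trapezoid area under the empirical ROC).  Constant
#' scores give exactly 0.5.
#'
#' @param scores numeric decision scores (here: the fraction of positive
#'   votes among the inner-loop classifiers).
#' @param labels -1/+1 vector.
#' @return list with `auc` and `roc` (data.frame of FPR/TPR points).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1)
  nneg <- sum(labels == -1)
  if (npos == 0 || nneg == 0) stop("roc_auc: both classes must be present")
  rk <- rank(scores)  # midranks handle ties
  auc <- (sum(rk[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  thr <- sort(unique(scores), decreasing = TRUE)
  roc <- data.frame(
    threshold = c(Inf, thr),
    FPR = c(0, vapply(thr, function(t) sum(scores >= t & labels == -1) / nneg,
                      numeric(1))),
    TPR = c(0, vapply(thr, function(t) sum(scores >= t & labels == 1) / npos,
                      numeric(1)))
  )
  list(auc = auc, roc = roc)
}

assemble_folds <- function(raw_folds, subject_ids, method, net_grid,
                           lasso_grid) {
  lapply(raw_folds, function(f) {
    inner <- lapply(f$inner, function(ii) {
      list(held_out_id = subject_ids[ii$held_out],
           net_lambda_rel = if (method == "pc") NA_real_ else net_grid[ii$net_index],
           lasso_lambda = lasso_grid[ii$lasso_index],
           inner_correct = ii$inner_correct,
           empty_selection = ii$empty_selection,
           selected = as.integer(ii$selected),
           svm_w = as.numeric(ii$svm_w),
           svm_b = ii$svm_b,
           vote = ii$vote)
    })
    structure(
      list(test_subject_id = subject_ids[f$test_index],
           truth = f$truth,
           votes = as.integer(f$votes),
           vote_fraction = f$vote_fraction,
           final_label = f$final_label,
           inner = inner),
      class = "fold_result"
    )
  })
}

#' Nested leave-one-out cross-validated classification
#'
#' For each outer fold one subject is held out for testing; the remaining
#' `N - 1` training subjects yield `N - 1` inner splits, each holding out one
#' more subject.  Per inner split and per grid point (network lambda x LASSO
#' lambda) connectivity networks are built from the `N - 2` subset only, the
#' held-out subjects being encoded without entering construction (for GSR
#' the group problem sees only the subset; held-out subjects are encoded on
#' the learned support by [encode_new_subject()]'s restricted fit).  Each
#' inner split contributes one classifier at its best grid point (inner
#' hold-out correctness; ties broken toward sparser models: non-empty
#' selections over the degenerate majority-class model, then larger LASSO
#' lambda, then larger network lambda), and the outer test subject is
#' classified by
#' majority vote of the `N - 1` classifiers (vote ties toward the patient
#' class +1).  The fraction of positive votes is the subject's ROC score.
#'
#' The network grid is relative: absolute penalties are
#' `net_grid * lambda_max` of the problem at hand (per subject for SR, per
#' training subset for GSR), which makes the grid scale-free.
#'
#' @param co a [cohort].
#' @param method `"pc"`, `"sr"`, or `"gsr"`.
#' @param net_grid relative network-lambda grid (ignored for PC).
#' @param lasso_grid LASSO grid on the standardized-feature scale.
#' @param C SVM soft-margin cost (fixed; not tuned).
#' @param verbose print per-fold progress.
#' @return An object of class `cv_result`: metrics (`ACC`, `SEN`, `SPE`,
#'   `AUC`), confusion `counts`, per-fold `folds`, `roc` points, the grids,
#'   and the subject order used.
#' @export
nested_loocv <- function(co, method = c("pc", "sr", "gsr"),
                         net_grid = c(0.1, 0.2, 0.3, 0.4, 0.5),
                         lasso_grid = seq(0.01, 0.1, by = 0.01),
                         C = 1, verbose = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(co, "cohort"))
  N <- length(co$subjects)
  if (N < 6) stop("nested_loocv: need at least 6 subjects")
  if (sum(co$labels == 1) < 3 || sum(co$labels == -1) < 3) {
    stop("nested_loocv: need at least 3 subjects per class")
  }
  if (method != "pc" && (length(net_grid) < 1 || any(net_grid <= 0))) {
    stop("nested_loocv: net_grid must be positive and nonempty")
  }
  if (length(lasso_grid) < 1 || any(lasso_grid <= 0)) {
    stop("nested_loocv: lasso_grid must be positive and nonempty")
  }
  net_grid <- sort(net_grid)
  lasso_grid <- sort(lasso_grid)

  # canonical subject order: results do not depend on manifest order
  ord <- order(co$subject_ids)
  subjects <- lapply(co$subjects[ord], ensure_conditioned)
  labels <- as.numeric(co$labels[ord])
  ids <- co$subject_ids[ord]
  R <- ncol(subjects[[1]]$data)
  Tn <- nrow(subjects[[1]]$data)

  svm_tol <- 1e-3; svm_max_pass <- 500L
  lasso_tol_rel <- 1e-6; lasso_max_iter <- 150L
  group_tol_rel <- 1e-6; group_max_iter <- 300L

  if (method == "gsr") {
    G <- gram_cube(subjects)
    eng <- cpp_cv_gsr(G, labels, net_grid, lasso_grid, C, svm_tol,
                      svm_max_pass, group_tol_rel, group_max_iter,
                      lasso_tol_rel, lasso_max_iter, 1e-6)
    raw_folds <- eng$folds
    n_ridge <- eng$n_ridge
  } else {
    if (method == "pc") {
      feats <- list(cohort_features(lapply(subjects, pearson_network)))
    } else {
      # per-subject SR networks at the subject-relative grid; the network of
      # a subject does not depend on which other subjects are in a subset
      feats <- vector("list", length(net_grid))
      desc <- rev(seq_along(net_grid))
      for (s in seq_len(N)) {
        lmax <- lambda_max_sr(subjects[[s]])
        Gs <- array(subject_gram(subjects[[s]]), dim = c(R, R, 1))
        path <- cpp_network_path(Gs, net_grid[desc] * lmax,
                                 group_tol_rel * (Tn - 1), group_max_iter)
        for (k in seq_along(net_grid)) {
          fin <- cpp_finalize_network(path$raw[[which(desc == k)]][, , 1])
          if (is.null(feats[[k]])) {
            feats[[k]] <- matrix(0, N, R * (R - 1) / 2)
          }
          feats[[k]][s, ] <- vectorize_upper_triangle(fin$matrix)
        }
      }
    }
    raw_folds <- cpp_cv_fixed(feats, labels, lasso_grid, C, svm_tol,
                              svm_max_pass, lasso_tol_rel, lasso_max_iter)
    n_ridge <- 0L
  }

  folds <- assemble_folds(raw_folds, ids, method, net_grid, lasso_grid)
  preds <- vapply(folds, function(f) f$final_label, numeric(1))
  fracs <- vapply(folds, function(f) f$vote_fraction, numeric(1))
  counts <- confusion_counts(labels, preds)
  metrics <- compute_metrics(counts)
  rocres <- roc_auc(fracs, labels)

  structure(
    list(method = toupper(method),
         metrics = list(ACC = metrics$ACC, SEN = metrics$SEN,
                        SPE = metrics$SPE, AUC = rocres$auc),
         counts = counts,
         folds = folds,
         roc = rocres$roc,
         vote_fractions = setNames(fracs, ids),
         final_labels = setNames(preds, ids),
         labels = setNames(labels, ids),
         subject_ids = ids,
         n_regions = R,
         net_grid = if (method == "pc") numeric(0) else net_grid,
         lasso_grid = lasso_grid,
         n_ridge = n_ridge),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<cv_result> %s nested LOOCV over %d subjects\n", x$method,
              length(x$subject_ids)))
  cat(sprintf("  ACC %.3f | SEN %.3f | SPE %.3f | AUC %.3f\n",
              m$ACC, m$SEN, m$SPE, m$AUC))
  cat(sprintf("  counts: TP %d FP %d FN %d TN %d\n", x$counts["TP"],
              x$counts["FP"], x$counts["FN"], x$counts["TN"]))
  invisible(x)
}
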