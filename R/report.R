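#' AAL-116 atlas table
#'
#' The Automated Anatomical Labeling atlas with 116 parcels: 1-based index,
#' short code, descriptive region name, and anatomical class (cortical,
#' subcortical = basal ganglia and thalamus, cerebellar = cerebellum and
#' vermis).
#'
#' @return data.frame with columns `index`, `code`, `name`, `class`.
#' @export
aal116_atlas <- function() {
  path <- system.file("extdata", "aal116.csv", package = "gsrnet")
  at <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(identical(at$index, 1:116), !anyDuplicated(at$name))
  at
}

#' Aggregate discriminative connections over cross-validation folds
#'
#' Every inner-loop classifier contributes its selected connections and SVM
#' weights.  For each connection, `frequency` is the number of classifiers
#' that selected it divided by the total number of inner classifiers across
#' all folds, and `mean_weight` is the mean of its SVM primal weights over
#' the classifiers that selected it.  Connections never selected are
#' omitted.
#'
#' @param cv a `cv_result` from [nested_loocv()], or its `folds` list (in
#'   which case `n_regions` must be given).
#' @param n_regions number of ROIs (taken from `cv` when available).
#' @return data.frame of class `discriminative_report` with columns
#'   `roi_i`, `roi_j`, `mean_weight`, `frequency`, `n_selected`, sorted by
#'   frequency; attributes `total_classifiers` and `n_regions`.
#' @export
aggregate_folds <- function(cv, n_regions = NULL) {
  if (inherits(cv, "cv_result")) {
    folds <- cv$folds
    n_regions <- cv$n_regions
  } else {
    folds <- cv
    if (is.null(n_regions)) stop("aggregate_folds: n_regions required")
  }
  if (length(folds) < 1) stop("aggregate_folds: no folds")
  P <- n_regions * (n_regions - 1) / 2
  count <- numeric(P)
  wsum <- numeric(P)
  total <- 0L
  for (f in folds) {
    for (ii in f$inner) {
      total <- total + 1L
      sel <- ii$selected
      if (length(sel) > 0) {
        count[sel] <- count[sel] + 1
        wsum[sel] <- wsum[sel] + ii$svm_w
      }
    }
  }
  if (total == 0) stop("aggregate_folds: no inner classifiers")
  keep <- which(count > 0)
  map <- upper_triangle_map(n_regions)
  rep <- data.frame(
    roi_i = map$roi_i[keep],
    roi_j = map$roi_j[keep],
    mean_weight = wsum[keep] / count[keep],
    frequency = count[keep] / total,
    n_selected = as.integer(count[keep])
  )
  rep <- sort_report(rep)
  structure(rep, class = c("discriminative_report", "data.frame"),
            total_classifiers = total, n_regions = n_regions)
}

# Deterministic ordering: frequency desc, |mean weight| desc, index pair asc.
sort_report <- function(rep) {
  o <- order(-rep$frequency, -abs(rep$mean_weight), rep$roi_i, rep$roi_j)
  rep <- rep[o, , drop = FALSE]
  rownames(rep) <- NULL
  rep
}

#' Filter a discriminative report
#'
#' Keeps either the top `k` connections by occurrence frequency or all
#' connections at or above a frequency threshold, in the deterministic order
#' of frequency (desc), absolute mean weight (desc), index pair (asc).
#'
#' @param report a `discriminative_report`.
#' @param k keep the top `k` rows (`k = 0` gives an empty report).
#' @param freq_threshold keep rows with `frequency >= freq_threshold`.
#' @return The filtered, sorted report (attributes preserved).
#' @export
select_top <- function(report, k = NULL, freq_threshold = NULL) {
  stopifnot(inherits(report, "discriminative_report"))
  at <- attributes(report)
  rep <- sort_report(as.data.frame(report))
  if (!is.null(freq_threshold)) {
    rep <- rep[rep$frequency >= freq_threshold, , drop = FALSE]
  }
  if (!is.null(k)) {
    rep <- head(rep, n = k)
  }
  rownames(rep) <- NULL
  structure(rep, class = c("discriminative_report", "data.frame"),
            total_classifiers = at$total_classifiers,
            n_regions = at$n_regions)
}

#' Name connections against an atlas
#'
#' Renders each connection as `(index_i, name_i, index_j, name_j)` and
#' derives the region roster: the unique ROIs appearing in the listed
#' connections, partitioned into cortical / subcortical / cerebellar counts.
#'
#' @param report a `discriminative_report`.
#' @param atlas an atlas table as from [aal116_atlas()].
#' @return list with `connections` (named data.frame) and `regions`
#'   (data.frame with `index`, `name`, `class`), plus `class_counts`.
#' @export
name_connections <- function(report, atlas = aal116_atlas()) {
  idx <- sort(unique(c(report$roi_i, report$roi_j)))
  unknown <- setdiff(idx, atlas$index)
  if (length(unknown) > 0) {
    stop("name_connections: unknown ROI index: ",
         paste(unknown, collapse = ", "))
  }
  nm <- setNames(atlas$name, atlas$index)
  cl <- setNames(atlas$class, atlas$index)
  connections <- data.frame(
    roi_i = report$roi_i,
    name_i = unname(nm[as.character(report$roi_i)]),
    roi_j = report$roi_j,
    name_j = unname(nm[as.character(report$roi_j)]),
    mean_weight = report$mean_weight,
    frequency = report$frequency
  )
  regions <- data.frame(index = idx,
                        name = unname(nm[as.character(idx)]),
                        class = unname(cl[as.character(idx)]))
  counts <- table(factor(regions$class,
                         levels = c("cortical", "subcortical", "cerebellar")))
  list(connections = connections, regions = regions,
       class_counts = as.list(counts))
}

#' Write a discriminative report as CSV (and optionally JSON)
#'
#' @param named output of [name_connections()].
#' @param csv_path CSV destination.
#' @param json_path optional JSON destination.
#' @return `csv_path`, invisibly.
#' @export
write_report <- function(named, csv_path, json_path = NULL) {
  write.csv(named$connections, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(named, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
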