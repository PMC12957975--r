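#' Cohort of subjects with binary group labels
#'
#' A cohort bundles per-subject [roi_timeseries] objects with group labels
#' encoded -1 (e.g. healthy controls) / +1 (e.g. patients, the positive
#' class) and, for synthetic cohorts, the generative ground truth.
#'
#' @param subjects list of [roi_timeseries] objects, all with the same ROIs.
#' @param labels integer vector of -1/+1 group labels, one per subject.
#' @param ground_truth optional ground-truth object from [generate_cohort()].
#' @return An object of class `cohort`.
#' @export
cohort <- function(subjects, labels, ground_truth = NULL) {
  stopifnot(is.list(subjects), length(subjects) >= 1)
  if (!all(vapply(subjects, inherits, logical(1), "roi_timeseries"))) {
    stop("cohort: all subjects must be roi_timeseries objects")
  }
  labels <- as.integer(labels)
  if (length(labels) != length(subjects)) {
    stop("cohort: one label per subject required")
  }
  if (!all(labels %in% c(-1L, 1L))) {
    stop("cohort: labels must be -1 or +1")
  }
  Rs <- vapply(subjects, function(s) ncol(s$data), integer(1))
  if (length(unique(Rs)) != 1) {
    stop("cohort: all subjects must share the same number of ROIs")
  }
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) stop("cohort: duplicate subject ids")
  structure(
    list(subjects = subjects, labels = labels, subject_ids = ids,
         ground_truth = ground_truth),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%d / %d per group), %d ROIs x %d time points\n",
              length(x$subjects), sum(x$labels == -1), sum(x$labels == 1),
              ncol(x$subjects[[1]]$data), nrow(x$subjects[[1]]$data)))
  if (!is.null(x$ground_truth)) cat("  with generative ground truth\n")
  invisible(x)
}

#' @export
length.cohort <- function(x) length(x$subjects)

condition_cohort <- function(co) {
  co$subjects <- lapply(co$subjects, ensure_conditioned)
  co
}

#' Write a cohort to disk
#'
#' Writes one delimited time-series file per subject plus a manifest CSV
#' (`subject_id`, `group`, `path`); synthetic ground truth, when present, is
#' written as JSON with 1-based ROI index pairs.
#'
#' @param co a [cohort].
#' @param dir output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(co, dir) {
  stopifnot(inherits(co, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(co$subjects))
  for (i in seq_along(co$subjects)) {
    paths[i] <- file.path(dir, paste0(co$subject_ids[i], ".tsv"))
    write_timeseries(co$subjects[[i]], paths[i])
  }
  manifest <- data.frame(subject_id = co$subject_ids, group = co$labels,
                         path = paths, stringsAsFactors = FALSE)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  if (!is.null(co$ground_truth)) {
    gt <- co$ground_truth
    jsonlite::write_json(
      list(support_edges = gt$support_edges, effect_edges = gt$effect_edges),
      file.path(dir, "ground_truth.json"), auto_unbox = FALSE
    )
  }
  invisible(mpath)
}

#' Read a cohort manifest and its time-series files
#'
#' @param manifest_path path to a manifest CSV with columns `subject_id`,
#'   `group`, `path` (paths resolved relative to the manifest's directory
#'   when not absolute).  `group` may be -1/+1 or two named labels, in which
#'   case `positive_label` names the +1 class.
#' @param positive_label optional label mapped to +1.
#' @return A [cohort].
#' @export
read_cohort <- function(manifest_path, positive_label = NULL) {
  if (!file.exists(manifest_path)) {
    stop("read_cohort: no such manifest: ", manifest_path)
  }
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  req <- c("subject_id", "group", "path")
  if (!all(req %in% names(man))) {
    stop("read_cohort: manifest must have columns subject_id, group, path")
  }
  if (anyDuplicated(man$subject_id)) stop("read_cohort: duplicate subject ids")
  grp <- man$group
  if (is.character(grp) && !all(grp %in% c("-1", "1", "+1"))) {
    lev <- sort(unique(grp))
    if (length(lev) != 2) stop("read_cohort: need exactly 2 group labels")
    if (is.null(positive_label)) positive_label <- lev[2]
    if (!positive_label %in% lev) {
      stop("read_cohort: positive_label not found among group labels")
    }
    labels <- ifelse(grp == positive_label, 1L, -1L)
  } else {
    labels <- as.integer(grp)
  }
  base <- dirname(manifest_path)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", man$path), man$path,
                  file.path(base, man$path))
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("read_cohort: unresolvable path(s): ",
         paste(paths[missing], collapse = ", "))
  }
  subjects <- Map(read_timeseries, paths, man$subject_id)
  names(subjects) <- NULL
  cohort(subjects, labels)
}
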