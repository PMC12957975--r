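#' Run configuration
#'
#' Bundles the method and tuning grids for a pipeline run.  Every run writes
#' its resolved configuration beside its outputs so results are reproducible
#' from (manifest, config, seed).
#'
#' @param method `"pc"`, `"sr"`, or `"gsr"`.
#' @param net_grid relative network-lambda grid (fractions of
#'   `lambda_max`; ignored for PC).
#' @param lasso_grid LASSO feature-selection grid.
#' @param C SVM soft-margin cost.
#' @param seed integer seed recorded with the run (the pipeline itself is
#'   deterministic; the seed matters when the manifest points at synthetic
#'   data regenerated elsewhere).
#' @param positive_label manifest group label mapped to +1 (patients).
#' @return A `run_config` list.
#' @export
run_config <- function(method = c("pc", "sr", "gsr"),
                       net_grid = c(0.1, 0.2, 0.3, 0.4, 0.5),
                       lasso_grid = seq(0.01, 0.1, by = 0.01),
                       C = 1, seed = 1L, positive_label = NULL) {
  method <- match.arg(method)
  if (length(lasso_grid) < 1 || any(lasso_grid <= 0)) {
    stop("run_config: lasso_grid must be positive and nonempty")
  }
  if (method != "pc" && (length(net_grid) < 1 || any(net_grid <= 0))) {
    stop("run_config: net_grid must be positive and nonempty")
  }
  structure(list(method = method, net_grid = net_grid,
                 lasso_grid = lasso_grid, C = C, seed = as.integer(seed),
                 positive_label = positive_label),
            class = "run_config")
}

#' Run the full classification pipeline
#'
#' Network construction, nested leave-one-out cross-validation, and
#' discriminative-connection aggregation for one method.  Writes exactly
#' five files to `out_dir`: `metrics.json` (ACC/SEN/SPE/AUC, confusion
#' counts, ROC points), `fold_results.json` (per-subject votes, chosen
#' lambdas, selected features), `discriminative_connections.csv`,
#' `config.json` (the resolved configuration), and `run.log`.
#'
#' @param manifest path to a cohort manifest CSV, or a [cohort] object.
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @param atlas atlas table used to name connections when the cohort has
#'   116 ROIs; smaller cohorts fall back to bare indices.
#' @return The `cv_result`, invisibly; side effect: the report bundle.
#' @export
run_pipeline <- function(manifest, config = run_config(), out_dir,
                         atlas = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, sprintf("[%s] %s",
                                       format(Sys.time(), "%H:%M:%S"), msg))
  }
  co <- tryCatch({
    if (inherits(manifest, "cohort")) manifest
    else read_cohort(manifest, positive_label = config$positive_label)
  }, error = function(e) {
    stop("pipeline stage 'load': ", conditionMessage(e))
  })
  say("loaded cohort: %d subjects, %d ROIs, %d time points",
      length(co$subjects), ncol(co$subjects[[1]]$data),
      nrow(co$subjects[[1]]$data))
  say("seed: %d", config$seed)

  cv <- tryCatch(
    nested_loocv(co, method = config$method, net_grid = config$net_grid,
                 lasso_grid = config$lasso_grid, C = config$C),
    error = function(e) stop("pipeline stage 'classify': ",
                             conditionMessage(e))
  )
  for (f in cv$folds) {
    lam_net <- vapply(f$inner, function(i) i$net_lambda_rel, numeric(1))
    lam_las <- vapply(f$inner, function(i) i$lasso_lambda, numeric(1))
    n_empty <- sum(vapply(f$inner, function(i) i$empty_selection, logical(1)))
    say("fold %s: final %+d (vote fraction %.2f), modal lambda_net %s, modal lambda_lasso %.2f, %d empty selections",
        f$test_subject_id, f$final_label, f$vote_fraction,
        if (all(is.na(lam_net))) "-" else format(stat_mode(lam_net)),
        stat_mode(lam_las), n_empty)
  }
  say("metrics: ACC %.3f SEN %.3f SPE %.3f AUC %.3f",
      cv$metrics$ACC, cv$metrics$SEN, cv$metrics$SPE, cv$metrics$AUC)
  if (cv$n_ridge > 0) say("ridge fallbacks during encoding: %d", cv$n_ridge)

  rep <- tryCatch(aggregate_folds(cv), error = function(e) {
    stop("pipeline stage 'report': ", conditionMessage(e))
  })
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  jsonlite::write_json(
    list(method = cv$method, metrics = cv$metrics,
         counts = as.list(cv$counts),
         vote_fractions = as.list(cv$vote_fractions),
         roc = cv$roc),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(
    lapply(cv$folds, unclass),
    file.path(out_dir, "fold_results.json"), auto_unbox = TRUE, digits = NA
  )
  if (cv$n_regions == 116) {
    if (is.null(atlas)) atlas <- aal116_atlas()
    named <- name_connections(rep, atlas)
    write.csv(named$connections,
              file.path(out_dir, "discriminative_connections.csv"),
              row.names = FALSE)
  } else {
    write.csv(as.data.frame(rep),
              file.path(out_dir, "discriminative_connections.csv"),
              row.names = FALSE)
  }
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  say("elapsed: %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(cv)
}

stat_mode <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA_real_)
  tb <- table(v)
  as.numeric(names(tb)[which.max(tb)])
}
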