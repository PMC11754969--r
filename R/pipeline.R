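#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: a cohort source (either a
#' [cohort_config()] to simulate or a path to a long-format RRI CSV), the
#' scaling regime, the classifier family, and the cross-validation shape.
#' Exactly one scaling regime must be chosen: the train-fold z-scaler and
#' personalized longitudinal scaling are mutually exclusive by design.
#'
#' @param cohort a [cohort_config()], an `hrv_cohort`, or `NULL` when
#'   `rri_path` is given.
#' @param rri_path optional path to an RRI CSV (see [read_rri_table()]).
#' @param scaling_mode one of `"train-zscore"`, `"longitudinal"`, `"none"`.
#' @param model `"random_forest"` or `"mlp"`.
#' @param k,repeats cross-validation shape.
#' @param run_stats also compute delta-HRV statistics (default TRUE).
#' @param run_shap collect Shapley attributions (random forest only; default
#'   same as `model == "random_forest"`).
#' @param seed master seed; all stage seeds derive from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), rri_path = NULL,
                            scaling_mode = "train-zscore",
                            model = "random_forest", k = 10L, repeats = 20L,
                            run_stats = TRUE, run_shap = NULL, seed = 1L) {
  if (length(scaling_mode) != 1L ||
      !scaling_mode %in% c("train-zscore", "longitudinal", "none")) {
    stop("choose exactly one scaling regime: train-zscore, longitudinal or none",
         call. = FALSE)
  }
  if (is.null(cohort) && is.null(rri_path)) {
    stop("provide a cohort (config or object) or an rri_path", call. = FALSE)
  }
  structure(list(cohort = cohort, rri_path = rri_path,
                 scaling_mode = scaling_mode, model = model, k = as.integer(k),
                 repeats = as.integer(repeats), run_stats = isTRUE(run_stats),
                 run_shap = run_shap %||% (model == "random_forest"),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulate (or ingest) -> artifact-correct -> extract the 20-feature battery
#' -> scale -> classify with subject-wise repeated cross-validation ->
#' aggregate Shapley importance -> delta-HRV group statistics. Every stage's
#' seed derives from the manifest seed, so rerunning with the same
#' configuration reproduces identical outputs. Warnings raised by the stages
#' are collected into the manifest. A stage failure aborts with the failing
#' stage named.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, stage outputs are written
#'   (features/metrics/importance/stats as CSV/JSON) along with
#'   `manifest.json`, and their MD5 digests recorded.
#' @return list with `features`, `cv`, `importance`, `delta_stats` and
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(package = "hrvstress",
                   version = as.character(packageVersion("hrvstress")),
                   created = format(Sys.time(), tz = "UTC"),
                   seed = config$seed,
                   scaling_mode = config$scaling_mode, model = config$model,
                   k = config$k, repeats = config$repeats,
                   warnings = character(0), digests = list())
  note <- function(w) {
    manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = note),
             error = function(e) {
               stop(sprintf("pipeline stage '%s' failed: %s", name,
                            conditionMessage(e)), call. = FALSE)
             })
  }
  cohort <- stage("ingest", {
    if (!is.null(config$rri_path)) {
      read_rri_table(config$rri_path)
    } else if (inherits(config$cohort, "hrv_cohort")) {
      config$cohort
    } else {
      cfg <- config$cohort
      cfg$seed <- config$seed
      generate_cohort(cfg)
    }
  })
  manifest$n_series <- length(cohort)
  features <- stage("extract", extract_cohort_features(cohort))
  spec <- model_spec(ifelse(config$model == "mlp", "mlp", "random_forest"),
                     seed = config$seed)
  cv <- stage("classify", repeated_cv(
    features, spec, k = config$k, repeats = config$repeats,
    scaling_mode = config$scaling_mode, base_seed = config$seed,
    collect_shap = config$run_shap))
  importance <- if (config$run_shap) {
    stage("interpret", aggregate_importance(
      cv, scope = "combined",
      regime = if (config$scaling_mode == "longitudinal") "scaled" else "raw"))
  }
  delta_stats <- if (config$run_stats) {
    stage("stats", {
      ft <- if (config$scaling_mode == "longitudinal") {
        longitudinal_scale(features)
      } else {
        features
      }
      regime <- if (config$scaling_mode == "longitudinal") "scaled" else "raw"
      reactivity_summary(delta_hrv(ft, regime = regime))
    })
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(features = file.path(out_dir, "features.csv"),
               metrics = file.path(out_dir, "metrics.csv"),
               importance = file.path(out_dir, "importance.csv"),
               delta_stats = file.path(out_dir, "delta_stats.csv"))
    write.csv(features, paths[["features"]], row.names = FALSE)
    write.csv(cv$metrics, paths[["metrics"]], row.names = FALSE)
    if (!is.null(importance)) write.csv(importance, paths[["importance"]], row.names = FALSE)
    if (!is.null(delta_stats)) write.csv(delta_stats, paths[["delta_stats"]], row.names = FALSE)
    written <- paths[file.exists(paths)]
    manifest$digests <- as.list(tools::md5sum(written))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(features = features, cv = cv, importance = importance,
       delta_stats = delta_stats, manifest = manifest)
}
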