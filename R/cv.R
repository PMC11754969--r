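#' Subject-wise repeated cross-validated classification
#'
#' The workhorse evaluation: `repeats` rounds of k-fold cross-validation with
#' a fresh subject-wise, group-stratified [assign_subject_folds()] plan per
#' round (seed `base_seed + repeat`). Within each round, one model is tuned
#' and fit per training fold and evaluated on the held-out fold; fold metrics
#' are averaged into a round-level value, and results are reported as mean and
#' SD over the rounds, overall and per clinical group. A runtime leakage guard
#' asserts that no participant ever appears in both train and test.
#'
#' Scaling regimes: `"train-zscore"` fits [fit_train_scaler()] inside each
#' training fold and applies it to the fold's test rows; `"longitudinal"`
#' applies [longitudinal_scale()] to the full feature table (all phases)
#' before any split and uses no train scaler; `"none"` uses the features as
#' given.
#'
#' @param feature_table wide table from [extract_cohort_features()]; all five
#'   phases should be present so the longitudinal statistics can use them.
#' @param spec a [model_spec()].
#' @param k outer folds (default 10).
#' @param repeats number of repeated rounds (default 20).
#' @param scaling_mode `"train-zscore"`, `"longitudinal"` or `"none"`.
#' @param base_seed integer; every random draw derives from it.
#' @param collect_shap also compute tree Shapley attributions on every test
#'   fold (random forest only).
#' @param features feature columns.
#' @return Object of class `cv_result`: `$metrics` (scope x metric mean/SD),
#'   `$per_repeat` (round-level values), and with `collect_shap` a
#'   `$shap` list of per-round importance summaries for
#'   [aggregate_importance()].
#' @export
repeated_cv <- function(feature_table, spec = model_spec("random_forest"),
                        k = 10L, repeats = 20L,
                        scaling_mode = c("train-zscore", "longitudinal", "none"),
                        base_seed = 1L, collect_shap = FALSE,
                        features = hrv_feature_names()) {
  scaling_mode <- match.arg(scaling_mode)
  if (collect_shap && spec$family != "random_forest") {
    stop("Shapley attributions are supported for the random forest only", call. = FALSE)
  }
  ft <- feature_table
  if (scaling_mode == "longitudinal") ft <- longitudinal_scale(ft, features)
  ds <- task_dataset(ft, features)
  per_repeat <- list()
  shap_by_repeat <- if (collect_shap) vector("list", repeats) else NULL
  for (r in seq_len(repeats)) {
    plan <- assign_subject_folds(ds, k = k, seed = base_seed + r)
    fold_metrics <- list()
    shap_abs_sum <- shap_sign_sum <- setNames(numeric(length(features)), features)
    shap_n <- 0L
    for (f in seq_len(k)) {
      test_p <- plan$participant[plan$fold == f]
      train <- ds[!ds$participant %in% test_p, , drop = FALSE]
      test <- ds[ds$participant %in% test_p, , drop = FALSE]
      if (length(intersect(train$participant, test$participant)) > 0L) {
        stop("leakage guard tripped: participant in both train and test", call. = FALSE)
      }
      if (nrow(test) == 0L) next
      if (scaling_mode == "train-zscore") {
        sc <- suppressWarnings(
          fit_train_scaler(train, features,
                           provenance = sprintf("repeat%d_fold%d", r, f)))
        train <- apply_scaler(train, sc)
        test <- apply_scaler(test, sc)
      }
      fit_seed <- base_seed + 1000L * r + f
      fold_spec <- spec
      fold_spec$seed <- fit_seed
      model <- if (spec$family == "random_forest") {
        tune_random_forest(train, fold_spec, features)
      } else {
        tune_mlp(train, fold_spec, features)
      }
      prob <- predict_prob(model, test)
      pred <- ifelse(prob >= 0.5, "stress", "relaxation")
      fold_metrics[[f]] <- evaluate(prob, pred, test$task, test$group)
      if (collect_shap) {
        sh <- tree_shapley(model, test, features)
        shap_abs_sum <- shap_abs_sum + colSums(abs(sh$phi))
        shap_sign_sum <- shap_sign_sum + colSums(sh$phi)
        shap_n <- shap_n + nrow(sh$phi)
      }
    }
    fm <- do.call(rbind, fold_metrics)
    agg <- stats::aggregate(fm[, c("accuracy", "f1", "recall", "precision", "auc")],
                            by = list(scope = fm$scope), FUN = mean, na.rm = TRUE)
    agg <- cbind(data.frame(rep = r), agg)
    per_repeat[[r]] <- agg
    if (collect_shap) {
      shap_by_repeat[[r]] <- list(mean_abs = shap_abs_sum / shap_n,
                                  mean_signed = shap_sign_sum / shap_n,
                                  n_rows = shap_n)
    }
  }
  pr <- do.call(rbind, per_repeat)
  metric_names <- c("accuracy", "f1", "recall", "precision", "auc")
  summ <- do.call(rbind, lapply(split(pr, pr$scope), function(d) {
    data.frame(scope = d$scope[1],
               metric = metric_names,
               mean = vapply(metric_names, function(m) mean(d[[m]], na.rm = TRUE), 0),
               sd = vapply(metric_names, function(m) sd(d[[m]]), 0),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(metrics = summ, per_repeat = pr, shap = shap_by_repeat,
                 spec = spec, k = k, repeats = repeats,
                 scaling_mode = scaling_mode, base_seed = base_seed,
                 features = features),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d-fold x %d repeats, scaling = %s\n",
              x$spec$family, x$k, x$repeats, x$scaling_mode))
  acc <- x$metrics[x$metrics$metric == "accuracy", ]
  for (i in seq_len(nrow(acc))) {
    cat(sprintf("  accuracy [%s]: %.4f +/- %.4f\n",
                acc$scope[i], acc$mean[i], acc$sd[i]))
  }
  invisible(x)
}

#' Convenience accessor for a summary metric
#'
#' @param x a `cv_result`.
#' @param metric metric name.
#' @param scope scope label (default `"overall"`).
#' @return The mean over repeats.
#' @export
cv_metric <- function(x, metric = "accuracy", scope = "overall") {
  m <- x$metrics
  m$mean[m$metric == metric & m$scope == scope]
}

#' One model per clinical group
#'
#' Splits the feature table by group and runs [repeated_cv()] on each subset
#' exclusively, so no cross-group rows enter any model (training or testing).
#'
#' @inheritParams repeated_cv
#' @return Named list of `cv_result`, one per group present.
#' @export
per_group_models <- function(feature_table, spec = model_spec("random_forest"),
                             k = 10L, repeats = 20L,
                             scaling_mode = c("train-zscore", "longitudinal", "none"),
                             base_seed = 1L, collect_shap = FALSE,
                             features = hrv_feature_names()) {
  scaling_mode <- match.arg(scaling_mode)
  groups <- intersect(GROUPS, unique(feature_table$group))
  out <- lapply(groups, function(g) {
    repeated_cv(feature_table[feature_table$group == g, , drop = FALSE],
                spec, k, repeats, scaling_mode, base_seed, collect_shap,
                features)
  })
  names(out) <- groups
  out
}
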