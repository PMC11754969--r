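#' Exact tree-path Shapley attributions for a fitted random forest
#'
#' Computes path-dependent TreeSHAP attributions of the predicted stress
#' probability for every row of `data`. Each tree of the probability forest
#' is exported (split structure from the fitted ensemble; node covers and
#' leaf values reconstructed by routing the training rows with their inbag
#' multiplicities) and the exact polynomial-time Shapley recursion is run in
#' C++. Attributions satisfy local accuracy: `base + rowSums(phi)` equals the
#' model's predicted probability for every row.
#'
#' @param model an `hrv_rf` from [tune_random_forest()].
#' @param data rows to explain (must contain the feature columns).
#' @param features feature columns.
#' @return list with `phi` (rows x features attribution matrix), `base`
#'   (expected prediction over the trees' cover distribution) and `pred`
#'   (`base + rowSums(phi)`).
#' @export
tree_shapley <- function(model, data, features = NULL) {
  if (!inherits(model, "hrv_rf")) {
    stop("unsupported model: Shapley attributions require a tree ensemble (hrv_rf)",
         call. = FALSE)
  }
  features <- features %||% model$features
  trees <- forest_trees(model)
  X <- as.matrix(data[, features, drop = FALSE])
  res <- .forest_shap(trees, X)
  phi <- res$phi
  colnames(phi) <- features
  list(phi = phi, base = res$base, pred = res$base + rowSums(phi))
}

# Export a ranger probability forest as parallel arrays with inbag covers and
# leaf values (fraction of the positive class among routed inbag rows).
forest_trees <- function(model) {
  if (!is.null(model$trees)) return(model$trees)
  fit <- model$fit
  if (is.null(fit$inbag.counts)) {
    stop("forest was fitted without inbag counts", call. = FALSE)
  }
  lapply(seq_len(fit$num.trees), function(t) {
    ti <- ranger::treeInfo(fit, t)
    left <- ifelse(is.na(ti$leftChild), -1L, as.integer(ti$leftChild))
    right <- ifelse(is.na(ti$rightChild), -1L, as.integer(ti$rightChild))
    feature <- ifelse(is.na(ti$splitvarID), 0L, as.integer(ti$splitvarID))
    threshold <- ifelse(is.na(ti$splitval), 0, as.numeric(ti$splitval))
    rt <- .tree_route(left, right, feature, threshold, model$train_x,
                      model$train_y, as.numeric(fit$inbag.counts[[t]]))
    list(left = left, right = right, feature = feature, threshold = threshold,
         value = as.numeric(rt$value), cover = as.numeric(rt$cover))
  })
}

#' Aggregate Shapley attributions into an importance report
#'
#' Mean absolute attribution per feature, first averaged within each repeat of
#' the cross-validation (over all of that repeat's test rows) and then across
#' repeats, ranked in descending order. Ties keep the canonical feature-name
#' ordering. The signed mean is reported alongside for direction inspection.
#'
#' @param shap_by_repeat list with one entry per repeat (as produced by
#'   [repeated_cv()] with `collect_shap = TRUE`, or a `cv_result`), each
#'   holding `mean_abs` and `mean_signed` per feature.
#' @param scope scope label stored in the report (default `"combined"`).
#' @param regime scaling regime label (default `"raw"`).
#' @return data.frame `feature`, `mean_abs_shap`, `mean_shap`, `rank`,
#'   `scope`, `regime`, ordered by rank; always one row per feature.
#' @export
aggregate_importance <- function(shap_by_repeat, scope = "combined",
                                 regime = "raw") {
  if (inherits(shap_by_repeat, "cv_result")) {
    shap_by_repeat <- shap_by_repeat$shap
  }
  if (is.null(shap_by_repeat)) {
    stop("no attributions present; run repeated_cv(collect_shap = TRUE)", call. = FALSE)
  }
  missing <- which(vapply(shap_by_repeat, is.null, TRUE))
  if (length(missing)) {
    stop("attributions missing for repeat(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  abs_mat <- do.call(rbind, lapply(shap_by_repeat, `[[`, "mean_abs"))
  sign_mat <- do.call(rbind, lapply(shap_by_repeat, `[[`, "mean_signed"))
  mean_abs <- colMeans(abs_mat)
  out <- data.frame(feature = names(mean_abs),
                    mean_abs_shap = unname(mean_abs),
                    mean_shap = unname(colMeans(sign_mat)),
                    stringsAsFactors = FALSE)
  # stable ranking: descending importance, ties by canonical feature order
  ord <- order(-out$mean_abs_shap, seq_len(nrow(out)))
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  out$scope <- scope
  out$regime <- regime
  rownames(out) <- NULL
  out
}

#' Bar plot of an importance report
#'
#' @param report output of [aggregate_importance()].
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot_importance <- function(report, ...) {
  r <- report[order(report$rank, decreasing = TRUE), ]
  graphics::barplot(r$mean_abs_shap, names.arg = r$feature, horiz = TRUE,
                    las = 1, xlab = "mean |Shapley attribution|", ...)
}
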