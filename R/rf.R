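#' Model specification for the classifiers
#'
#' @param family `"random_forest"` or `"mlp"`.
#' @param grid hyperparameter grid. For the random forest, an integer vector
#'   of tree counts (default `c(50, 100, 200)`); for the MLP, a data.frame
#'   with list-column `hidden` and column `learning_rate` (default the six
#'   combinations of architectures `(4,8,16)` and `(4,8,16,32)` with initial
#'   learning rates `1e-4`, `1e-3`, `1e-2`).
#' @param inner_k inner cross-validation folds for the grid search (default
#'   5; also subject-wise).
#' @param seed integer seed.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("random_forest", "mlp"), grid = NULL,
                       inner_k = 5L, seed = 1L) {
  family <- match.arg(family)
  if (is.null(grid)) {
    grid <- if (family == "random_forest") {
      c(50L, 100L, 200L)
    } else {
      mlp_default_grid()
    }
  }
  if (length(grid) == 0L || (is.data.frame(grid) && nrow(grid) == 0L)) {
    stop("hyperparameter grid must be non-empty", call. = FALSE)
  }
  structure(list(family = family, grid = grid, inner_k = as.integer(inner_k),
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Default MLP grid: two architectures x three initial learning rates
#'
#' Ordered simplest-first (smaller architecture, then smaller learning rate)
#' so grid-search ties resolve to the simpler model.
#'
#' @return data.frame with list-column `hidden` and `learning_rate` (6 rows).
#' @export
mlp_default_grid <- function() {
  g <- expand.grid(arch = 1:2, lr = c(1e-4, 1e-3, 1e-2))
  g <- g[order(g$arch, g$lr), ]
  data.frame(
    hidden = I(lapply(g$arch, function(a) if (a == 1) c(4L, 8L, 16L) else c(4L, 8L, 16L, 32L))),
    learning_rate = g$lr
  )
}

inner_fold_accuracy <- function(train, fit_fun, inner_k, seed,
                                features = hrv_feature_names()) {
  plan <- assign_subject_folds(train, k = inner_k, seed = seed)
  accs <- vapply(seq_len(inner_k), function(f) {
    test_p <- plan$participant[plan$fold == f]
    tr <- train[!train$participant %in% test_p, , drop = FALSE]
    te <- train[train$participant %in% test_p, , drop = FALSE]
    if (length(unique(tr$task)) < 2L || nrow(te) == 0L) return(NA_real_)
    fit <- fit_fun(tr)
    mean((predict_prob(fit, te) >= 0.5) == (te$task == "stress"))
  }, 0)
  mean(accs, na.rm = TRUE)
}

#' Grid-tuned random forest for stress-vs-relaxation
#'
#' Searches the tree-count grid by subject-wise inner cross-validation on the
#' training rows only, then refits a probability forest (ranger) with the best
#' count on all training rows. Ties resolve to the smallest tree count.
#' Non-grid hyperparameters stay at the library defaults (Gini impurity,
#' sqrt(p) candidate features per split, unlimited depth); they are recorded
#' on the returned object.
#'
#' @param train training rows (a [task_dataset()] subset).
#' @param spec a [model_spec()] with `family = "random_forest"`.
#' @param features feature columns.
#' @return An object of class `hrv_rf` exposing class-probability prediction
#'   via [predict_prob()].
#' @export
tune_random_forest <- function(train, spec = model_spec("random_forest"),
                               features = hrv_feature_names()) {
  if (length(unique(train$task)) < 2L) {
    stop("training set contains a single class", call. = FALSE)
  }
  grid <- as.integer(spec$grid)
  inner <- if (length(grid) > 1L) {
    vapply(grid, function(nt) {
      inner_fold_accuracy(train, function(tr) {
        fit_ranger(tr, nt, spec$seed, features)
      }, spec$inner_k, spec$seed, features)
    }, 0)
  } else {
    NA_real_
  }
  best <- if (length(grid) > 1L) grid[which.max(inner)] else grid[1L]
  fit <- fit_ranger(train, best, spec$seed, features, keep_inbag = TRUE)
  structure(list(fit = fit, num_trees = best, inner_accuracy = inner,
                 grid = grid, features = features,
                 train_x = as.matrix(train[, features]),
                 train_y = as.numeric(train$task == "stress"),
                 defaults = list(splitrule = "gini", mtry = "sqrt(p)",
                                 max_depth = "unlimited")),
            class = "hrv_rf")
}

fit_ranger <- function(train, num_trees, seed, features, keep_inbag = FALSE) {
  ranger::ranger(
    x = train[, features, drop = FALSE],
    y = factor(train$task, levels = c("relaxation", "stress")),
    num.trees = num_trees, probability = TRUE, seed = seed,
    num.threads = 1L, keep.inbag = keep_inbag
  )
}

#' Positive-class (stress) probability
#'
#' @param model an `hrv_rf` or `hrv_mlp`.
#' @param data rows with the model's feature columns.
#' @return numeric vector of P(stress).
#' @export
predict_prob <- function(model, data) UseMethod("predict_prob")

#' @export
predict_prob.hrv_rf <- function(model, data) {
  p <- predict(model$fit, data[, model$features, drop = FALSE],
               num.threads = 1L)$predictions
  unname(p[, "stress"])
}

#' @export
predict_prob.ranger <- function(model, data) {
  vars <- model$forest$independent.variable.names
  p <- predict(model, data[, vars, drop = FALSE], num.threads = 1L)$predictions
  unname(p[, "stress"])
}
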