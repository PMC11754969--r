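#' Fit a dense multilayer perceptron for binary classification
#'
#' Fully-connected ReLU hidden layers, sigmoid output, binary cross-entropy
#' loss with an L2 weight penalty, trained full-batch with Adam. A
#' subject-wise 10% slice of the training rows is held out for early
#' stopping: training stops when the validation score (negative log-loss) has
#' not improved by at least `tol` for `patience` consecutive epochs (best
#' weights restored),
#' or after `max_iter` epochs, in which case the best-so-far model is
#' returned with a warning. No dropout is used.
#'
#' @param x numeric matrix of predictors (rows = samples).
#' @param y numeric 0/1 response (1 = stress).
#' @param participants subject identifier per row, used for the subject-wise
#'   validation split; `NULL` falls back to a row-wise split.
#' @param hidden integer vector of hidden-layer widths.
#' @param learning_rate initial Adam learning rate.
#' @param l2 L2 penalty coefficient (default 1e-4).
#' @param max_iter maximum epochs (default 1000).
#' @param tol minimum validation-score improvement (default 1e-4).
#' @param patience epochs without improvement before stopping (default 10).
#' @param val_frac validation fraction (default 0.1).
#' @param seed integer seed for the split and the weight initialisation.
#' @return Object of class `mlp_fit` with `predict_prob()` support.
#' @export
mlp_fit <- function(x, y, participants = NULL, hidden = c(4L, 8L, 16L),
                    learning_rate = 1e-3, l2 = 1e-4, max_iter = 1000L,
                    tol = 1e-4, patience = 10L, val_frac = 0.1, seed = 1L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y))
  with_seed(seed, {
    n <- nrow(x)
    if (is.null(participants)) participants <- as.character(seq_len(n))
    ids <- unique(participants)
    val_ids <- sample(ids, max(1L, ceiling(val_frac * length(ids))))
    vi <- participants %in% val_ids
    if (all(vi) || !any(vi)) vi <- seq_len(n) %in% sample(n, max(1L, round(val_frac * n)))
    xtr <- x[!vi, , drop = FALSE]; ytr <- y[!vi]
    xva <- x[vi, , drop = FALSE]; yva <- y[vi]

    sizes <- c(ncol(x), hidden, 1L)
    nl <- length(sizes) - 1L
    W <- lapply(seq_len(nl), function(l) {
      matrix(rnorm(sizes[l] * sizes[l + 1L], 0, sqrt(2 / sizes[l])),
             sizes[l], sizes[l + 1L])
    })
    b <- lapply(seq_len(nl), function(l) numeric(sizes[l + 1L]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(bb) bb * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; epsa <- 1e-8
    forward <- function(X) {
      acts <- vector("list", nl + 1L)
      acts[[1L]] <- X
      for (l in seq_len(nl)) {
        z <- sweep(acts[[l]] %*% W[[l]], 2, b[[l]], "+")
        acts[[l + 1L]] <- if (l < nl) pmax(z, 0) else 1 / (1 + exp(-z))
      }
      acts
    }
    best <- list(W = W, b = b, score = -Inf, epoch = 0L)
    stall <- 0L
    converged <- FALSE
    ntr <- nrow(xtr)
    for (epoch in seq_len(max_iter)) {
      acts <- forward(xtr)
      p <- acts[[nl + 1L]]
      delta <- (p - ytr) / ntr        # dL/dz for sigmoid + BCE
      gW <- vector("list", nl); gb <- vector("list", nl)
      for (l in rev(seq_len(nl))) {
        gW[[l]] <- crossprod(acts[[l]], delta) + l2 * W[[l]] / ntr
        gb[[l]] <- colSums(delta)
        if (l > 1L) {
          delta <- (delta %*% t(W[[l]])) * (acts[[l]] > 0)
        }
      }
      for (l in seq_len(nl)) {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
        mhW <- mW[[l]] / (1 - beta1^epoch); vhW <- vW[[l]] / (1 - beta2^epoch)
        mhb <- mb[[l]] / (1 - beta1^epoch); vhb <- vb[[l]] / (1 - beta2^epoch)
        W[[l]] <- W[[l]] - learning_rate * mhW / (sqrt(vhW) + epsa)
        b[[l]] <- b[[l]] - learning_rate * mhb / (sqrt(vhb) + epsa)
      }
      pv <- forward(xva)[[nl + 1L]]
      pv <- pmin(pmax(pv, 1e-12), 1 - 1e-12)
      score <- mean(yva * log(pv) + (1 - yva) * log(1 - pv)) # negative log-loss
      if (score > best$score + tol) {
        best <- list(W = W, b = b, score = score, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) { converged <- TRUE; break }
      }
    }
    if (!converged) {
      warning("MLP reached max_iter without early stopping; returning best-so-far weights")
    }
    structure(list(W = best$W, b = best$b, hidden = hidden,
                   learning_rate = learning_rate, l2 = l2,
                   val_score = best$score, epochs = best$epoch,
                   features = colnames(x)),
              class = "mlp_fit")
  })
}

mlp_forward_prob <- function(model, x) {
  a <- as.matrix(x)
  nl <- length(model$W)
  for (l in seq_len(nl)) {
    z <- sweep(a %*% model$W[[l]], 2, model$b[[l]], "+")
    a <- if (l < nl) pmax(z, 0) else 1 / (1 + exp(-z))
  }
  as.numeric(a)
}

#' @export
predict_prob.mlp_fit <- function(model, data) {
  mlp_forward_prob(model, data[, model$features, drop = FALSE])
}

#' Grid-tuned multilayer perceptron
#'
#' Same protocol as [tune_random_forest()]: the six (architecture x learning
#' rate) combinations are scored by subject-wise inner cross-validation on the
#' training rows, the winner refit on all training rows. Ties resolve to the
#' earlier grid row (smaller architecture, then smaller learning rate).
#'
#' @param train training rows (a [task_dataset()] subset).
#' @param spec a [model_spec()] with `family = "mlp"`.
#' @param features feature columns.
#' @return Object of class `hrv_mlp`.
#' @export
tune_mlp <- function(train, spec = model_spec("mlp"),
                     features = hrv_feature_names()) {
  if (length(unique(train$task)) < 2L) {
    stop("training set contains a single class", call. = FALSE)
  }
  grid <- spec$grid
  fit_one <- function(tr, row) {
    mlp_fit(tr[, features], as.numeric(tr$task == "stress"),
            participants = tr$participant, hidden = grid$hidden[[row]],
            learning_rate = grid$learning_rate[row], seed = spec$seed)
  }
  inner <- if (nrow(grid) > 1L) {
    vapply(seq_len(nrow(grid)), function(row) {
      inner_fold_accuracy(train, function(tr) fit_one(tr, row),
                          spec$inner_k, spec$seed, features)
    }, 0)
  } else {
    NA_real_
  }
  best_row <- if (nrow(grid) > 1L) which.max(inner) else 1L
  fit <- suppressWarnings(fit_one(train, best_row))
  structure(list(fit = fit, hidden = grid$hidden[[best_row]],
                 learning_rate = grid$learning_rate[best_row],
                 inner_accuracy = inner, grid = grid, features = features),
            class = "hrv_mlp")
}

#' @export
predict_prob.hrv_mlp <- function(model, data) {
  mlp_forward_prob(model$fit, data[, model$features, drop = FALSE])
}
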