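#' Fit a train-set z-scaler
#'
#' Per-feature mean and sample SD computed on training rows only; the same
#' statistics are later applied to test rows ([apply_scaler()]) so no test
#' information enters the transform. Constant features (SD 0) are passed
#' through as zeros with a warning.
#'
#' @param train data.frame of training rows.
#' @param features feature columns (default the 20-feature battery).
#' @param provenance free-text origin label (e.g. fold id) stored with the
#'   statistics for leakage audits.
#' @return An object of class `scaler_stats`.
#' @export
fit_train_scaler <- function(train, features = hrv_feature_names(),
                             provenance = "train") {
  if (nrow(train) < 2L) stop("need at least 2 training samples", call. = FALSE)
  mu <- vapply(features, function(f) mean(train[[f]]), 0)
  sdv <- vapply(features, function(f) sd(train[[f]]), 0)
  if (any(sdv == 0)) {
    warning("constant feature column(s) pass through as 0: ",
            paste(features[sdv == 0], collapse = ", "))
  }
  structure(list(mean = mu, sd = sdv, features = features,
                 provenance = provenance),
            class = "scaler_stats")
}

#' Apply fitted z-scaling statistics
#'
#' @param data data.frame containing the scaler's feature columns.
#' @param stats a `scaler_stats` from [fit_train_scaler()].
#' @return `data` with the feature columns standardised by the stored
#'   statistics (constant features mapped to 0).
#' @export
apply_scaler <- function(data, stats) {
  stopifnot(inherits(stats, "scaler_stats"))
  for (f in stats$features) {
    data[[f]] <- if (stats$sd[[f]] > 0) {
      (data[[f]] - stats$mean[[f]]) / stats$sd[[f]]
    } else {
      rep(0, nrow(data))
    }
  }
  data
}

#' Personalized longitudinal scaling
#'
#' Z-scores every feature within participant, using all of that participant's
#' records (all phases of all retained visits): for participant p and feature
#' f, the scaled value is `(x - mean_p(f)) / sd_p(f)`. This deliberately uses
#' each participant's full longitudinal record — including sessions that later
#' fall into test folds — and is applied before any train/test split; when it
#' is used, the train-set z-scaler is not. Participants with fewer than 2
#' records are excluded with a warning (scaling them would fabricate
#' constants). Idempotent: scaling an already-scaled table is a no-op.
#'
#' @param data feature table (one row per participant/visit/phase).
#' @param features feature columns.
#' @return The table with features scaled within participant; participants
#'   with a single record removed.
#' @export
longitudinal_scale <- function(data, features = hrv_feature_names()) {
  counts <- table(data$participant)
  single <- names(counts)[counts < 2]
  if (length(single)) {
    warning(sprintf("excluding %d participant(s) with < 2 records: %s",
                    length(single), paste(single, collapse = ", ")))
    data <- data[!data$participant %in% single, , drop = FALSE]
  }
  for (f in features) {
    mu <- ave(data[[f]], data$participant, FUN = function(v) mean(v, na.rm = TRUE))
    sdv <- ave(data[[f]], data$participant, FUN = function(v) sd(v, na.rm = TRUE))
    sdv[sdv == 0 | is.na(sdv)] <- 1  # constant-within-participant: centre only
    data[[f]] <- (data[[f]] - mu) / sdv
  }
  rownames(data) <- NULL
  data
}
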