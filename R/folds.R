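#' Subject-wise, group-stratified fold assignment
#'
#' Partitions participants (never rows) into `k` folds so that no individual
#' spans train and test. Within each clinical group participants are dealt
#' evenly (fold group counts differ by at most 1) and the remainders are
#' placed on the currently smallest folds, so total fold sizes also differ by
#' at most 1. Because every session contributes one stress and one relaxation
#' row, task balance within folds is automatic under subject-wise splitting.
#'
#' @param participants data.frame with columns `participant` and `group`
#'   (one row per participant), or a dataset from which the unique pairs are
#'   taken.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return data.frame `participant`, `group`, `fold` (1..k) with attributes
#'   `k` and `seed`; class `fold_plan`.
#' @export
assign_subject_folds <- function(participants, k = 10L, seed = 1L) {
  pp <- unique(participants[, c("participant", "group")])
  if (nrow(pp) < k) {
    stop(sprintf("need at least %d participants for %d folds", k, k), call. = FALSE)
  }
  with_seed(seed, {
    fold <- integer(nrow(pp))
    totals <- integer(k)
    for (g in unique(pp$group)) {
      idx <- sample(which(pp$group == g))
      n <- length(idx)
      base <- n %/% k
      rem <- n %% k
      sizes <- rep(base, k)
      if (rem > 0) {
        # give the extras to the folds that are currently smallest
        ord <- order(totals, sample(k))
        sizes[ord[seq_len(rem)]] <- base + 1L
      }
      f <- rep(seq_len(k), times = sizes)
      fold[idx] <- f
      totals <- totals + tabulate(f, k)
    }
    out <- data.frame(participant = pp$participant, group = pp$group,
                      fold = fold, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    structure(out, k = k, seed = seed, class = c("fold_plan", "data.frame"))
  })
}

#' Build the labeled stress/relaxation dataset from a feature table
#'
#' Keeps the stress and relaxation rows (the two task phases), renames the
#' phase column to `task`, and drops rows with missing feature values
#' (listwise, with a message reporting the count) so that no incomplete row
#' enters a model. Stress is the positive class throughout.
#'
#' @param feature_table output of [extract_cohort_features()] (optionally
#'   scaled).
#' @param features feature columns.
#' @return data.frame `participant`, `group`, `visit`, `task`, features.
#' @export
task_dataset <- function(feature_table, features = hrv_feature_names()) {
  d <- feature_table[feature_table$phase %in% TASKS, , drop = FALSE]
  d$task <- d$phase
  d <- d[, c("participant", "group", "visit", "task", features)]
  ok <- complete.cases(d[, features])
  if (any(!ok)) {
    message(sprintf("dropping %d row(s) with missing feature values", sum(!ok)))
    d <- d[ok, , drop = FALSE]
  }
  rownames(d) <- NULL
  d
}

#' Random undersampling to the smallest group
#'
#' Samples sessions (participant-visits) without replacement within each group
#' down to the smallest group's session count, so the stress/relaxation pair
#' of a session is kept or dropped together.
#'
#' @param dataset a [task_dataset()].
#' @param seed integer seed.
#' @return The undersampled dataset.
#' @export
undersample <- function(dataset, seed = 1L) {
  skey <- paste(dataset$participant, dataset$visit, sep = "\r")
  sess <- unique(data.frame(key = skey, group = dataset$group,
                            stringsAsFactors = FALSE))
  target <- min(table(sess$group))
  keep <- with_seed(seed, {
    unlist(lapply(split(sess$key, sess$group), function(keys) {
      sample(keys, target)
    }), use.names = FALSE)
  })
  out <- dataset[skey %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
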