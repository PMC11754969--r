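# In-code fixtures: a direct feature-table generator (no RRI simulation) for
# the scaling / classification / statistics tests, plus small cohort configs.

phases5 <- c("rest1", "stress", "rest2", "relaxation", "rest3")

# Feature rows with controllable subject offsets, visit drift and task
# effects. `task_effect` is a named vector added to stress rows (or a
# function(group) returning one) on the named features; all other variation
# is N(0, noise_sd) plus per-participant and per-visit offsets shared across
# that participant's rows.
toy_feature_table <- function(n_per_group = c(MDD = 6, PD = 6, HC = 8),
                              visits = 3,
                              task_effect = c(mean_rri = -1),
                              subject_sd = 1, drift_sd = 0, noise_sd = 0.3,
                              seed = 1) {
  feats <- hrv_feature_names()
  set.seed(seed)
  rows <- list()
  pnum <- 0
  for (g in names(n_per_group)) {
    eff <- if (is.function(task_effect)) task_effect(g) else task_effect
    for (i in seq_len(n_per_group[[g]])) {
      pnum <- pnum + 1
      id <- sprintf("S%03d", pnum)
      subj <- rnorm(length(feats), 0, subject_sd)
      for (v in seq_len(visits)) {
        drift <- rnorm(length(feats), 0, drift_sd)
        for (ph in phases5) {
          val <- subj + drift + rnorm(length(feats), 0, noise_sd)
          if (ph == "stress") val[match(names(eff), feats)] <- val[match(names(eff), feats)] + eff
          row <- data.frame(participant = id, group = g, visit = v, phase = ph,
                            stringsAsFactors = FALSE)
          row[feats] <- as.list(val)
          rows[[length(rows) + 1]] <- row
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Tiny labelled dataset with two informative features for classifier tests.
toy_labeled <- function(n_participants = 30, visits = 2, sep = 2, seed = 1) {
  set.seed(seed)
  grp <- rep(c("MDD", "PD", "HC"), length.out = n_participants)
  rows <- list()
  for (i in seq_len(n_participants)) {
    for (v in seq_len(visits)) {
      for (task in c("stress", "relaxation")) {
        mu <- if (task == "stress") sep else -sep
        rows[[length(rows) + 1]] <- data.frame(
          participant = sprintf("Q%03d", i), group = grp[i], visit = v,
          task = task, x1 = rnorm(1, mu), x2 = rnorm(1),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

quiet_cv <- function(...) suppressWarnings(suppressMessages(repeated_cv(...)))
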