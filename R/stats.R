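#' Within-subject task differences (delta-HRV)
#'
#' For every participant-visit where both task rows exist, the stress value
#' minus the relaxation value of each feature — the session-level autonomic
#' reactivity. Visits missing either task are skipped and their count
#' reported via a message. When applied to longitudinally scaled features the
#' differences are taken after scaling (scale first, then difference).
#'
#' @param feature_table wide feature table with a `phase` column.
#' @param features feature columns.
#' @param regime label recorded on the result (`"raw"` or `"scaled"`).
#' @return data.frame `participant`, `group`, `visit`, `regime` and one
#'   delta column per feature.
#' @export
delta_hrv <- function(feature_table, features = hrv_feature_names(),
                      regime = "raw") {
  str <- feature_table[feature_table$phase == "stress", , drop = FALSE]
  rlx <- feature_table[feature_table$phase == "relaxation", , drop = FALSE]
  key <- function(d) paste(d$participant, d$visit, sep = "\r")
  common <- intersect(key(str), key(rlx))
  skipped <- length(unique(c(key(str), key(rlx)))) - length(common)
  if (skipped > 0) {
    message(sprintf("skipping %d session(s) missing one of the two tasks", skipped))
  }
  str <- str[match(common, key(str)), , drop = FALSE]
  rlx <- rlx[match(common, key(rlx)), , drop = FALSE]
  out <- str[, c("participant", "group", "visit")]
  out$regime <- regime
  for (f in features) out[[f]] <- str[[f]] - rlx[[f]]
  rownames(out) <- NULL
  out
}

#' Paired t-test between the two tasks
#'
#' Two-sided paired-samples t-test of stress versus relaxation values;
#' differences with zero variance are flagged degenerate rather than tested.
#'
#' @param stress_values,relax_values paired numeric vectors.
#' @return list `t`, `p`, `df`, `mean_diff`, `degenerate`.
#' @export
paired_ttest <- function(stress_values, relax_values) {
  stopifnot(length(stress_values) == length(relax_values))
  ok <- complete.cases(stress_values, relax_values)
  d <- stress_values[ok] - relax_values[ok]
  if (length(d) < 2L) stop("need at least 2 pairs", call. = FALSE)
  if (sd(d) == 0) {
    # identical pairs: no effect and no variance -> t = 0, p = 1; a nonzero
    # constant difference is flagged degenerate (t undefined)
    if (mean(d) == 0) {
      return(list(t = 0, p = 1, df = length(d) - 1L, mean_diff = 0,
                  degenerate = FALSE))
    }
    return(list(t = NA_real_, p = NA_real_, df = length(d) - 1L,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- t.test(stress_values[ok], relax_values[ok], paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_diff = mean(d), degenerate = FALSE)
}

games_howell <- function(values, groups) {
  gs <- split(values, groups)
  k <- length(gs)
  pairs <- utils::combn(names(gs), 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr) {
    a <- gs[[pr[1]]]; b <- gs[[pr[2]]]
    na <- length(a); nb <- length(b)
    se2 <- var(a) / na + var(b) / nb
    t <- abs(mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((var(a) / na)^2 / (na - 1) + (var(b) / nb)^2 / (nb - 1))
    p <- ptukey(t * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
    data.frame(pair = paste(pr, collapse = "-"), p = p, stringsAsFactors = FALSE)
  }))
}

bonferroni_pairwise <- function(values, groups) {
  gs <- split(values, groups)
  k <- length(gs)
  n <- length(values)
  # pooled error variance from the one-way decomposition (the classical
  # Bonferroni post-hoc): MSE with N - k df
  mse <- sum(vapply(gs, function(v) sum((v - mean(v))^2), 0)) / (n - k)
  pairs <- utils::combn(names(gs), 2, simplify = FALSE)
  m <- length(pairs)
  do.call(rbind, lapply(pairs, function(pr) {
    a <- gs[[pr[1]]]; b <- gs[[pr[2]]]
    t <- abs(mean(a) - mean(b)) / sqrt(mse * (1 / length(a) + 1 / length(b)))
    p_raw <- 2 * pt(t, df = n - k, lower.tail = FALSE)
    data.frame(pair = paste(pr, collapse = "-"), p = min(1, m * p_raw),
               stringsAsFactors = FALSE)
  }))
}

cohens_d_pooled <- function(a, b) {
  sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (length(a) + length(b) - 2))
  if (sp == 0) return(0)
  abs(mean(a) - mean(b)) / sp
}

#' Homogeneity-routed one-way ANOVA with post-hoc tests
#'
#' Compares one feature's values among the three groups. Variance homogeneity
#' is assessed with the Brown-Forsythe test (median-centred Levene) at alpha
#' 0.05; when homogeneous, Fisher's one-way ANOVA with Bonferroni-adjusted
#' pairwise t-tests (pooled error variance) is used, otherwise Welch's ANOVA
#' with Games-Howell pairwise comparisons. Eta squared is reported from the
#' Fisher sums-of-squares decomposition in both routes, and pairwise Cohen's
#' d uses the pooled SD of each pair.
#'
#' @param values numeric vector.
#' @param group_labels group per value (3 groups, >= 2 observations each).
#' @param alpha homogeneity threshold (default 0.05).
#' @return Object of class `anova_result`: list with `F`, `p`, `eta_sq`,
#'   `homogeneity_p`, `route`, and `posthoc` (pair, p, d).
#' @export
group_anova <- function(values, group_labels, alpha = 0.05) {
  ok <- is.finite(values)
  values <- values[ok]
  group_labels <- as.character(group_labels)[ok]
  gs <- split(values, group_labels)
  if (length(gs) < 3L) stop("need 3 groups", call. = FALSE)
  if (any(vapply(gs, length, 0L) < 2L)) {
    stop("need at least 2 observations per group", call. = FALSE)
  }
  g <- factor(group_labels)
  zerovar <- all(vapply(gs, function(v) var(v) == 0, TRUE))
  hom_p <- if (zerovar) 1 else car::leveneTest(values ~ g, center = median)[1, "Pr(>F)"]
  homogeneous <- hom_p >= alpha
  grand <- mean(values)
  ssb <- sum(vapply(gs, function(v) length(v) * (mean(v) - grand)^2, 0))
  sst <- sum((values - grand)^2)
  eta_sq <- if (sst > 0) ssb / sst else 0
  if (sst == 0) {
    fstat <- 0; pval <- 1
  } else if (homogeneous) {
    ow <- oneway.test(values ~ g, var.equal = TRUE)
    fstat <- unname(ow$statistic); pval <- ow$p.value
  } else {
    ow <- oneway.test(values ~ g, var.equal = FALSE)
    fstat <- unname(ow$statistic); pval <- ow$p.value
  }
  post <- if (sst == 0) {
    pairs <- utils::combn(names(gs), 2, simplify = FALSE)
    do.call(rbind, lapply(pairs, function(pr) {
      data.frame(pair = paste(pr, collapse = "-"), p = 1, stringsAsFactors = FALSE)
    }))
  } else if (homogeneous) {
    bonferroni_pairwise(values, group_labels)
  } else {
    games_howell(values, group_labels)
  }
  post$d <- vapply(strsplit(post$pair, "-"), function(pr) {
    cohens_d_pooled(gs[[pr[1]]], gs[[pr[2]]])
  }, 0)
  structure(list(F = fstat, p = pval, eta_sq = eta_sq, homogeneity_p = hom_p,
                 route = if (homogeneous) "Fisher+Bonferroni" else "Welch+Games-Howell",
                 posthoc = post),
            class = "anova_result")
}

#' Per-feature group comparison of autonomic reactivity
#'
#' For every feature: the group means of the stress-minus-relaxation
#' differences, the homogeneity-routed ANOVA ([group_anova()]), and a
#' direction label (e.g. `"HC > MDD, PD"`) comparing absolute reactivity,
#' assigned only where the main effect and the relevant post-hoc pairwise
#' comparisons are significant at `alpha`.
#'
#' @param delta_records output of [delta_hrv()].
#' @param features feature columns.
#' @param alpha significance level (default 0.05).
#' @return data.frame with one row per feature: group means, `F`, `p`,
#'   `eta_sq`, `route`, pairwise p and d columns, `direction`.
#' @export
reactivity_summary <- function(delta_records, features = hrv_feature_names(),
                               alpha = 0.05) {
  groups <- intersect(GROUPS, unique(delta_records$group))
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  rows <- lapply(features, function(f) {
    v <- delta_records[[f]]
    ok <- is.finite(v)
    an <- group_anova(v[ok], delta_records$group[ok])
    means <- vapply(groups, function(g) mean(v[ok & delta_records$group == g]), 0)
    absm <- vapply(groups, function(g) abs(mean(v[ok & delta_records$group == g])), 0)
    direction <- ""
    if (an$p < alpha) {
      # which groups dominate in |mean delta|, supported by significant post-hocs
      sigpairs <- an$posthoc$pair[an$posthoc$p < alpha]
      if (length(sigpairs)) {
        winners <- losers <- character(0)
        for (pr in strsplit(sigpairs, "-")) {
          w <- pr[which.max(absm[pr])]
          l <- setdiff(pr, w)
          winners <- union(winners, w)
          losers <- union(losers, l)
        }
        winners <- setdiff(winners, losers)
        if (length(winners)) {
          beaten <- unique(unlist(lapply(strsplit(sigpairs, "-"), function(pr) {
            if (any(pr %in% winners)) setdiff(pr, winners)
          })))
          direction <- paste(paste(winners, collapse = ", "), ">",
                             paste(sort(beaten), collapse = ", "))
        }
      }
    }
    row <- data.frame(feature = f, stringsAsFactors = FALSE)
    for (g in groups) row[[paste0("mean_", g)]] <- means[[g]]
    row$F <- an$F
    row$p <- an$p
    row$eta_sq <- an$eta_sq
    row$route <- an$route
    for (i in seq_len(nrow(an$posthoc))) {
      row[[paste0("p_", an$posthoc$pair[i])]] <- an$posthoc$p[i]
      row[[paste0("d_", an$posthoc$pair[i])]] <- an$posthoc$d[i]
    }
    row$direction <- direction
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
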