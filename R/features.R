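#' Canonical HRV feature names
#'
#' The fixed ordering of the 20-feature battery: six time-domain, seven
#' frequency-domain, two Poincare, two entropy, two DFA and one correlation
#' dimension measure.
#'
#' @return Character vector of length 20.
#' @export
hrv_feature_names <- function() {
  c("mean_rri", "sdnn", "rmssd", "pnn50", "tri", "tinn",
    "log_vlf", "log_lf", "log_hf", "log_tot", "lf_nu", "hf_nu", "lf_hf",
    "sd1", "sd2", "apen", "sampen", "alpha1", "alpha2", "cordim")
}

#' Extract the 20-feature HRV battery from one phase
#'
#' Applies [time_domain_features()], [spectral_features()], [poincare()],
#' [approximate_entropy()], [sample_entropy()], [dfa()] and
#' [correlation_dimension()] to a single phase's RR intervals and returns the
#' features in canonical order ([hrv_feature_names()]). Deterministic: the
#' same series always yields the same vector. Degenerate inputs follow the
#' package conventions (zero-variance series: entropies 0, SD1/SD2 0, TRI 1;
#' undefined SampEn reported as `NA`).
#'
#' @param rri an [rri_series()] or numeric vector of RR intervals (ms). The
#'   series is expected to have passed [correct_artifacts()].
#' @param entropy an [entropy_params()].
#' @param cordim_m,cordim_delay embedding settings for the correlation
#'   dimension.
#' @return Named numeric vector of length 20.
#' @export
extract_features <- function(rri, entropy = entropy_params(),
                             cordim_m = 10L, cordim_delay = 1L) {
  x <- if (inherits(rri, "rri_series")) rri$intervals_ms else as.numeric(rri)
  td <- time_domain_features(x)
  sp <- suppressWarnings(spectral_features(x))
  pc <- poincare(x)
  df <- dfa(x)
  out <- c(
    mean_rri = td$mean_rri, sdnn = td$sdnn, rmssd = td$rmssd,
    pnn50 = td$pnn50, tri = td$tri, tinn = td$tinn,
    log_vlf = sp$log_vlf, log_lf = sp$log_lf, log_hf = sp$log_hf,
    log_tot = sp$log_tot, lf_nu = sp$lf_nu, hf_nu = sp$hf_nu,
    lf_hf = sp$lf_hf,
    sd1 = pc$sd1, sd2 = pc$sd2,
    apen = approximate_entropy(x, entropy),
    sampen = sample_entropy(x, entropy),
    alpha1 = df$alpha1, alpha2 = df$alpha2,
    cordim = correlation_dimension(x, cordim_m, cordim_delay)
  )
  out[hrv_feature_names()]
}

#' Extract features for every series of a cohort
#'
#' Runs artifact correction (optional) and [extract_features()] over all
#' series, returning a wide table with one row per (participant, visit,
#' phase). Series failing the artifact-quality check are dropped with a
#' warning naming them; sub-operation errors are re-raised tagged with the
#' offending participant/visit/phase. Rows with undefined SampEn are kept
#' (value `NA`) and their count reported via a warning so downstream listwise
#' exclusion is visible.
#'
#' @param cohort an `hrv_cohort`.
#' @param correct run [correct_artifacts()] first (default TRUE).
#' @param dev_threshold artifact deviation threshold.
#' @param entropy an [entropy_params()].
#' @return data.frame with columns `participant`, `group`, `visit`, `phase`
#'   and the 20 canonical feature columns.
#' @export
extract_cohort_features <- function(cohort, correct = TRUE,
                                    dev_threshold = 0.25,
                                    entropy = entropy_params()) {
  rows <- vector("list", length(cohort))
  dropped <- character(0)
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    tag <- sprintf("%s/visit %d/%s", s$participant_id, s$visit, s$phase)
    feats <- tryCatch({
      if (correct) s <- correct_artifacts(s, dev_threshold)
      extract_features(s, entropy)
    }, error = function(e) {
      if (grepl("rejected", conditionMessage(e))) {
        dropped <<- c(dropped, tag)
        NULL
      } else {
        stop(sprintf("[%s] %s", tag, conditionMessage(e)), call. = FALSE)
      }
    })
    if (is.null(feats)) next
    rows[[i]] <- data.frame(participant = s$participant_id, group = s$group,
                            visit = s$visit, phase = s$phase,
                            as.list(feats), stringsAsFactors = FALSE)
  }
  if (length(dropped)) {
    warning(sprintf("%d series rejected by artifact quality check: %s",
                    length(dropped), paste(dropped, collapse = "; ")))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  n_na <- sum(is.na(out$sampen))
  if (n_na > 0) {
    warning(sprintf("SampEn undefined (no template matches) in %d series", n_na))
  }
  out
}
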