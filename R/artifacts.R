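#' Automated artifact correction of an RRI series
#'
#' Flags intervals deviating from an 11-beat running median by more than
#' `dev_threshold` (as a fraction of that median) — the usual signature of
#' ectopic beats and detection errors — and replaces them by piecewise cubic
#' spline interpolation over beat index through the unflagged beats. The
#' number of corrections is recorded in the `"n_corrected"` attribute.
#'
#' @param rri an [rri_series()] (or bare numeric vector of intervals in ms)
#'   with at least 11 beats.
#' @param dev_threshold fractional deviation threshold (default 0.25).
#' @param max_flagged_frac reject the series (quality error) when more than
#'   this fraction of beats is flagged (default 0.3).
#' @return The corrected series of the same class, with attributes
#'   `n_corrected` and `corrected_idx`.
#' @export
correct_artifacts <- function(rri, dev_threshold = 0.25, max_flagged_frac = 0.3) {
  x <- if (inherits(rri, "rri_series")) rri$intervals_ms else as.numeric(rri)
  n <- length(x)
  if (n < 11L) stop("artifact correction needs at least 11 beats", call. = FALSE)
  med <- stats::runmed(x, k = 11L, endrule = "median")
  flagged <- abs(x - med) > dev_threshold * med
  if (mean(flagged) > max_flagged_frac) {
    stop(sprintf("series rejected: %.0f%% of beats flagged as artifacts (limit %.0f%%)",
                 100 * mean(flagged), 100 * max_flagged_frac), call. = FALSE)
  }
  if (any(flagged)) {
    good <- which(!flagged)
    x[flagged] <- spline(good, x[good], xout = which(flagged), method = "natural")$y
    if (any(x <= 0)) x[x <= 0] <- med[x <= 0]
  }
  out <- if (inherits(rri, "rri_series")) {
    rri$intervals_ms <- x
    rri
  } else {
    x
  }
  attr(out, "n_corrected") <- sum(flagged)
  attr(out, "corrected_idx") <- which(flagged)
  out
}
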