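#' Resample an RRI tachogram to an equidistant grid
#'
#' Cubic-spline interpolates the series of RR intervals (s) against cumulative
#' beat time and samples it at `fs` Hz between the first and last beat.
#'
#' @param x RR intervals in ms.
#' @param fs sampling rate in Hz (default 4).
#' @return list with `t` (s) and `y` (RR values in s) on the uniform grid.
#' @export
resample_rri <- function(x, fs = 4) {
  x <- as.numeric(x) / 1000
  tt <- cumsum(x)
  grid <- seq(tt[1], tt[length(tt)], by = 1 / fs)
  list(t = grid, y = spline(tt, x, xout = grid, method = "fmm")$y)
}

#' Welch power spectral density
#'
#' Mean-removed signal split into Hann-windowed segments of `window_s` seconds
#' with 50% overlap; one-sided modified periodograms are averaged. If the
#' signal is shorter than one window a single-segment periodogram is returned
#' with a warning.
#'
#' @param y equidistantly sampled signal.
#' @param fs sampling rate (Hz).
#' @param window_s segment length in seconds (default 150).
#' @return list with `freq` (Hz) and `psd` (signal units squared per Hz).
#' @export
welch_psd <- function(y, fs = 4, window_s = 150) {
  y <- y - mean(y)
  n <- length(y)
  nper <- round(window_s * fs)
  if (n < nper) {
    warning("signal shorter than one Welch window; using a single segment")
    nper <- n
  }
  step <- max(floor(nper / 2), 1L)
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nper) - 1) / nper)  # periodic Hann
  scale <- fs * sum(w^2)
  nfreq <- floor(nper / 2) + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- y[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(fft(seg))^2 / scale
    p <- p[seq_len(nfreq)]
    p[2:(nfreq - 1L)] <- 2 * p[2:(nfreq - 1L)]
    if (nper %% 2 == 1L) p[nfreq] <- 2 * p[nfreq]
    acc <- acc + p
  }
  list(freq = (seq_len(nfreq) - 1L) * fs / nper, psd = acc / length(starts))
}

band_power <- function(freq, psd, lo, hi) {
  i <- which(freq >= lo & freq < hi)
  if (length(i) < 2L) return(0)
  sum(diff(freq[i]) * (psd[i][-1] + psd[i][-length(i)]) / 2)
}

#' Frequency-domain HRV features
#'
#' The tachogram is spline-resampled at 4 Hz ([resample_rri()]), its Welch PSD
#' estimated ([welch_psd()]; Hann windows of 150 s, 50% overlap), and band
#' powers integrated by trapezoid over VLF (0-0.04 Hz), LF (0.04-0.15 Hz) and
#' HF (0.15-0.4 Hz). Absolute powers are returned as natural logarithms of
#' power in s^2; relative powers as normalised units `lf_nu = 100 LF/(LF+HF)`
#' and `hf_nu = 100 HF/(LF+HF)`, plus the LF/HF ratio. Zero power in a band
#' yields `-Inf` logs; zero HF power flags `lf_hf` as `NA` with a warning.
#'
#' @param x RR intervals in ms spanning at least 60 s.
#' @param fs resampling rate (Hz).
#' @param window_s Welch window length (s).
#' @return Named list `log_vlf`, `log_lf`, `log_hf`, `log_tot` (ln s^2),
#'   `lf_nu`, `hf_nu` (0-100), `lf_hf`.
#' @export
spectral_features <- function(x, fs = 4, window_s = 150) {
  if (sum(x) / 1000 < 60) {
    stop("spectral features need at least 60 s of data", call. = FALSE)
  }
  rs <- resample_rri(x, fs)
  ps <- welch_psd(rs$y, fs, window_s)
  vlf <- band_power(ps$freq, ps$psd, 0, 0.04)
  lf <- band_power(ps$freq, ps$psd, 0.04, 0.15)
  hf <- band_power(ps$freq, ps$psd, 0.15, 0.4)
  tot <- vlf + lf + hf
  if (hf <= 0) warning("zero HF power: LF/HF undefined")
  lfhf <- if (hf > 0) lf / hf else NA_real_
  denom <- lf + hf
  list(
    log_vlf = log(vlf), log_lf = log(lf), log_hf = log(hf), log_tot = log(tot),
    lf_nu = if (denom > 0) 100 * lf / denom else NA_real_,
    hf_nu = if (denom > 0) 100 * hf / denom else NA_real_,
    lf_hf = lfhf
  )
}
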