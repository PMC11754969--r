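#' Time-domain HRV features
#'
#' Computes the six time-domain measures from one phase's RR intervals:
#' mean RRI (s), SDNN (ms, sample SD), RMSSD (ms), pNN50 (%), the triangular
#' index TRI (total beat count over the modal histogram bin count) and TINN
#' (ms, the baseline width of the least-squares triangular fit to the RRI
#' histogram). The histogram uses the conventional 1/128-s bin width; TINN is
#' found by exhaustive search of the left and right baseline points on the bin
#' grid (the two sides separate, so each is optimised independently).
#'
#' @param x numeric vector of RR intervals in ms (>= 2 values).
#' @return Named list `mean_rri` (s), `sdnn`, `rmssd` (ms), `pnn50` (%),
#'   `tri`, `tinn` (ms).
#' @export
time_domain_features <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("time-domain features need at least 2 intervals", call. = FALSE)
  d <- diff(x)
  geom <- rri_histogram_fit(x)
  list(
    mean_rri = mean(x) / 1000,
    sdnn = sd(x),
    rmssd = sqrt(mean(d^2)),
    pnn50 = 100 * mean(abs(d) > 50),
    tri = geom$tri,
    tinn = geom$tinn
  )
}

# Histogram-based geometric measures on the 1/128-s (7.8125 ms) bin grid.
rri_histogram_fit <- function(x) {
  bw <- 1000 / 128
  lo <- floor(min(x) / bw) * bw
  hi <- ceiling(max(x) / bw + 1e-9) * bw
  if (hi <= lo) hi <- lo + bw
  breaks <- seq(lo, hi, by = bw)
  if (length(breaks) < 2L) breaks <- c(lo, lo + bw)
  counts <- as.numeric(table(cut(x, breaks = breaks, include.lowest = TRUE,
                                 right = FALSE)))
  mids <- (head(breaks, -1) + breaks[-1]) / 2
  peak <- which.max(counts)
  tri <- length(x) / counts[peak]
  if (length(counts) == 1L || sum(counts > 0) == 1L) {
    return(list(tri = tri, tinn = 0, counts = counts, mids = mids))
  }
  # Triangular fit T(X): 0 outside [N, M], linear from (N, 0) up to the peak
  # (mids[peak], counts[peak]) and down to (M, 0). The squared error splits
  # into a left part depending only on N and a right part depending only on M.
  yp <- counts[peak]
  xp <- mids[peak]
  sse_side <- function(cand, side_idx) {
    # cand: candidate baseline abscissas; returns SSE over the side bins
    vapply(cand, function(b) {
      tvals <- if (b == xp) {
        rep(0, length(side_idx))
      } else {
        pmax(0, pmin(1, (mids[side_idx] - b) / (xp - b))) * yp
      }
      sum((counts[side_idx] - tvals)^2)
    }, 0)
  }
  left_idx <- seq_len(peak - 1)
  right_idx <- if (peak < length(counts)) (peak + 1):length(counts) else integer(0)
  n_cand <- c(breaks[seq_len(peak)], xp)
  n_best <- if (length(left_idx)) {
    sse <- sse_side(n_cand, left_idx)
    # prefer the narrowest triangle among equal-error fits
    n_cand[max(which(sse == min(sse)))]
  } else {
    xp
  }
  m_cand <- c(xp, breaks[(peak + 1):length(breaks)])
  m_best <- if (length(right_idx)) {
    sse <- vapply(m_cand, function(b) {
      tvals <- if (b == xp) {
        rep(0, length(right_idx))
      } else {
        pmax(0, pmin(1, (b - mids[right_idx]) / (b - xp))) * yp
      }
      sum((counts[right_idx] - tvals)^2)
    }, 0)
    m_cand[min(which(sse == min(sse)))]
  } else {
    xp
  }
  list(tri = tri, tinn = max(m_best - n_best, 0), counts = counts, mids = mids)
}

#' Poincare plot descriptors
#'
#' Dispersion of the lagged scatter of successive RR intervals perpendicular
#' to (SD1) and along (SD2) the line of identity. The identity-exact
#' convention is used: `sd1^2 = mean(diff(x)^2) / 2` (so `sd1 = rmssd /
#' sqrt(2)` holds exactly) and `sd2^2 = 2 sdnn^2 - sd1^2`.
#'
#' @param x numeric vector of RR intervals in ms (>= 3 values).
#' @return Named list with `sd1` and `sd2` (ms).
#' @export
poincare <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3L) stop("Poincare descriptors need at least 3 intervals", call. = FALSE)
  sd1sq <- mean(diff(x)^2) / 2
  sd2sq <- max(2 * var(x) - sd1sq, 0)
  list(sd1 = sqrt(sd1sq), sd2 = sqrt(sd2sq))
}
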