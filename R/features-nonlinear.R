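#' Entropy parameters
#'
#' Embedding dimension and tolerance used by [approximate_entropy()] and
#' [sample_entropy()]. The tolerance is `r_factor` times the sample SD of the
#' analysed segment (so r adapts to each series, the usual HRV convention).
#'
#' @param m embedding dimension (default 2).
#' @param r_factor tolerance as a fraction of the series SD (default 0.2).
#' @export
entropy_params <- function(m = 2L, r_factor = 0.2) {
  if (m < 1L) stop("`m` must be >= 1", call. = FALSE)
  if (r_factor <= 0) stop("`r_factor` must be > 0", call. = FALSE)
  list(m = as.integer(m), r_factor = r_factor)
}

embed_series <- function(x, m, delay = 1L) {
  n <- length(x) - (m - 1L) * delay
  sapply(seq_len(m), function(k) x[seq_len(n) + (k - 1L) * delay])
}

# counts, per template, of templates within Chebyshev distance r (self included)
cheb_counts <- function(E, r) {
  D <- as.matrix(stats::dist(E, method = "maximum"))
  rowSums(D <= r)
}

#' Approximate entropy
#'
#' Pincus' ApEn: `Phi_m(r) - Phi_{m+1}(r)` with self-matches included, where
#' `Phi_m(r)` is the mean log fraction of length-`m` templates lying within
#' Chebyshev distance `r` of each template. A zero-variance series returns 0
#' by convention.
#'
#' @param x numeric series (length >= m + 2).
#' @param params an [entropy_params()].
#' @return ApEn (dimensionless).
#' @export
approximate_entropy <- function(x, params = entropy_params()) {
  x <- as.numeric(x)
  m <- params$m
  if (length(x) < m + 2L) stop("series too short for ApEn", call. = FALSE)
  r <- params$r_factor * sd(x)
  if (r == 0) return(0)
  phi <- function(mm) {
    E <- embed_series(x, mm)
    cnt <- cheb_counts(E, r)
    mean(log(cnt / nrow(E)))
  }
  phi(m) - phi(m + 1L)
}

#' Sample entropy
#'
#' Richman & Moorman's SampEn: `-ln(A/B)` where `B` and `A` count pairs of
#' distinct templates of length `m` and `m + 1` within Chebyshev distance `r`
#' (self-matches excluded; both counts over the first `N - m` template
#' positions). A zero-variance series returns 0; `A = 0` (or `B = 0`) is
#' reported as `NA` — an undefined value, never silently substituted.
#'
#' @inheritParams approximate_entropy
#' @return SampEn, or `NA` when undefined.
#' @export
sample_entropy <- function(x, params = entropy_params()) {
  x <- as.numeric(x)
  m <- params$m
  if (length(x) < m + 2L) stop("series too short for SampEn", call. = FALSE)
  r <- params$r_factor * sd(x)
  if (r == 0) return(0)
  n_t <- length(x) - m  # templates of both lengths taken at positions 1..n_t
  Em <- embed_series(x, m)[seq_len(n_t), , drop = FALSE]
  Em1 <- embed_series(x, m + 1L)
  B <- sum(stats::dist(Em, method = "maximum") <= r)
  A <- sum(stats::dist(Em1, method = "maximum") <= r)
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

#' Detrended fluctuation analysis
#'
#' The mean-centred series is integrated; for every box size `n` the profile
#' is split into non-overlapping boxes (tail beats beyond the last full box
#' discarded), linearly detrended per box, and the RMS fluctuation `F(n)`
#' computed over all retained points. `alpha1` and `alpha2` are the
#' least-squares slopes of `log F(n)` against `log n` over box sizes 4-16 and
#' 17-64. White noise gives alpha near 0.5, Brownian motion near 1.5.
#'
#' @param x numeric series, length >= 130 (so the 64-beat boxes are populated).
#' @param short,long integer box-size ranges for the two exponents.
#' @return list with `alpha1`, `alpha2` and the `fluctuation` table
#'   (`n`, `F`).
#' @export
dfa <- function(x, short = 4:16, long = 17:64) {
  x <- as.numeric(x)
  need <- 2L * max(long)
  if (length(x) < max(130L, need)) {
    stop(sprintf("DFA needs at least %d beats", max(130L, need)), call. = FALSE)
  }
  if (sd(x) == 0) {
    return(list(alpha1 = 0, alpha2 = 0,
                fluctuation = data.frame(n = c(short, long), F = 0)))
  }
  y <- cumsum(x - mean(x))
  sizes <- c(short, long)
  Fv <- vapply(sizes, function(n) {
    nb <- floor(length(y) / n)
    Y <- matrix(y[seq_len(n * nb)], nrow = n)
    X <- cbind(1, seq_len(n))
    Q <- diag(n) - X %*% solve(crossprod(X), t(X))
    R <- Q %*% Y
    sqrt(mean(R^2))
  }, 0)
  fit_alpha <- function(rng) {
    i <- sizes %in% rng
    unname(coef(lm(log(Fv[i]) ~ log(sizes[i])))[2])
  }
  list(alpha1 = fit_alpha(short), alpha2 = fit_alpha(long),
       fluctuation = data.frame(n = sizes, F = Fv))
}

#' Grassberger-Procaccia correlation dimension
#'
#' The series is delay-embedded, the correlation sum `C(r)` (fraction of
#' distinct vector pairs closer than `r`, Euclidean) evaluated on a
#' log-spaced radius grid spanning the observed distances, and the dimension
#' estimated as the slope of `log C(r)` versus `log r` over the middle third
#' of radii with `0 < C(r) < 1` (the central scaling region). A constant
#' series returns 0.
#'
#' @param x numeric series.
#' @param embed_m embedding dimension (default 10).
#' @param delay embedding delay in beats (default 1).
#' @param n_radii size of the radius grid (default 30).
#' @return Correlation dimension estimate (dimensionless).
#' @export
correlation_dimension <- function(x, embed_m = 10L, delay = 1L, n_radii = 30L) {
  x <- as.numeric(x)
  if (length(x) < embed_m * delay + 50L) {
    stop("series too short for the correlation dimension", call. = FALSE)
  }
  if (sd(x) == 0) return(0)
  E <- embed_series(x, embed_m, delay)
  d <- stats::dist(E)
  dpos <- d[d > 0]
  if (length(dpos) < 2L) return(0)
  radii <- exp(seq(log(min(dpos)), log(max(dpos)), length.out = n_radii))
  cs <- correlation_sums(d, radii)
  ok <- which(cs > 0 & cs < 1)
  if (length(ok) < 2L) return(0)
  third <- max(1L, floor(length(ok) / 3))
  mid <- ok[seq.int(third, min(length(ok), 2L * third))]
  if (length(mid) < 2L) mid <- ok
  unname(coef(lm(log(cs[mid]) ~ log(radii[mid])))[2])
}

#' Correlation sums over a radius grid
#'
#' `C(r)` = fraction of distinct pairs with distance `< r`.
#'
#' @param d a `dist` object or numeric vector of pairwise distances.
#' @param radii radius grid.
#' @return numeric vector of `C(r)` values.
#' @export
correlation_sums <- function(d, radii) {
  d <- as.numeric(d)
  vapply(radii, function(r) mean(d < r), 0)
}
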