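# Literal-definition oracles: deliberately naive O(N^2) double loops and
# exhaustive enumerations, kept independent of the package's vectorised
# implementations.

apen_oracle <- function(x, m = 2L, r_factor = 0.2) {
  r <- r_factor * sd(x)
  N <- length(x)
  phi <- function(mm) {
    n <- N - mm + 1L
    logC <- numeric(n)
    for (i in seq_len(n)) {
      cnt <- 0L
      for (j in seq_len(n)) {
        if (max(abs(x[i:(i + mm - 1L)] - x[j:(j + mm - 1L)])) <= r) cnt <- cnt + 1L
      }
      logC[i] <- log(cnt / n)
    }
    mean(logC)
  }
  phi(m) - phi(m + 1L)
}

sampen_oracle <- function(x, m = 2L, r_factor = 0.2) {
  r <- r_factor * sd(x)
  N <- length(x)
  A <- 0L
  B <- 0L
  for (i in seq_len(N - m - 1L)) {
    for (j in (i + 1L):(N - m)) {
      if (max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)])) <= r) B <- B + 1L
      if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) A <- A + 1L
    }
  }
  if (A == 0L || B == 0L) return(NA_real_)
  -log(A / B)
}

dfa_fluctuation_oracle <- function(x, n) {
  y <- cumsum(x - mean(x))
  nb <- floor(length(y) / n)
  res <- numeric(0)
  for (b in seq_len(nb)) {
    seg <- y[((b - 1L) * n + 1L):(b * n)]
    tt <- seq_len(n)
    res <- c(res, stats::resid(stats::lm(seg ~ tt)))
  }
  sqrt(mean(res^2))
}

dfa_alpha_oracle <- function(x, sizes) {
  Fv <- vapply(sizes, function(n) dfa_fluctuation_oracle(x, n), 0)
  unname(stats::coef(stats::lm(log(Fv) ~ log(sizes)))[2])
}

corr_sums_oracle <- function(x, m, delay, radii) {
  n <- length(x) - (m - 1L) * delay
  E <- sapply(seq_len(m), function(k) x[seq_len(n) + (k - 1L) * delay])
  ds <- numeric(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ds <- c(ds, sqrt(sum((E[i, ] - E[j, ])^2)))
    }
  }
  vapply(radii, function(r) mean(ds < r), 0)
}

# Cover-weighted conditional expectation of a tree given the features in S,
# then Shapley values by exhaustive subset enumeration (0-based tree arrays
# as used by the package's C++ kernel).
tree_value_oracle <- function(tree, x, S) {
  rec <- function(node) {
    if (tree$left[node] < 0) return(tree$value[node])
    f <- tree$feature[node] + 1L
    l <- tree$left[node] + 1L
    r <- tree$right[node] + 1L
    if (f %in% S) {
      if (x[f] <= tree$threshold[node]) rec(l) else rec(r)
    } else {
      (tree$cover[l] * rec(l) + tree$cover[r] * rec(r)) / tree$cover[node]
    }
  }
  rec(1L)
}

shapley_oracle <- function(tree, x, p) {
  phi <- numeric(p)
  for (i in seq_len(p)) {
    others <- setdiff(seq_len(p), i)
    subsets <- list(integer(0))
    for (k in seq_along(others)) {
      subsets <- c(subsets, utils::combn(others, k, simplify = FALSE))
    }
    for (S in subsets) {
      w <- factorial(length(S)) * factorial(p - length(S) - 1L) / factorial(p)
      phi[i] <- phi[i] +
        w * (tree_value_oracle(tree, x, c(S, i)) - tree_value_oracle(tree, x, S))
    }
  }
  phi
}

fisher_f_oracle <- function(values, groups) {
  gs <- split(values, groups)
  k <- length(gs)
  n <- length(values)
  grand <- mean(values)
  ssb <- sum(vapply(gs, function(v) length(v) * (mean(v) - grand)^2, 0))
  ssw <- sum(vapply(gs, function(v) sum((v - mean(v))^2), 0))
  (ssb / (k - 1)) / (ssw / (n - k))
}
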