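#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact (O(n^2)) t-SNE. Input affinities are computed here from the data
// matrix via the usual per-point binary search for the bandwidth matching
// the target perplexity; the layout is optimised by gradient descent with
// momentum, adaptive gains and early exaggeration. The initial layout Y0 is
// drawn in R so all randomness stays under the caller's seed.
// [[Rcpp::export(name = ".tsne_exact")]]
NumericMatrix tsne_exact(NumericMatrix X, NumericMatrix Y0, double perplexity,
                         int max_iter) {
  const int n = X.nrow(), d = X.ncol();
  // squared Euclidean distances
  std::vector<double> D2((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0;
      for (int k = 0; k < d; ++k) {
        double diff = X(i, k) - X(j, k);
        s += diff * diff;
      }
      D2[(size_t)i * n + j] = s;
      D2[(size_t)j * n + i] = s;
    }
  }
  // conditional affinities at the requested perplexity
  std::vector<double> P((size_t)n * n, 0.0);
  const double logU = std::log(perplexity);
  for (int i = 0; i < n; ++i) {
    double beta = 1.0, betamin = -1e300, betamax = 1e300;
    std::vector<double> row(n);
    for (int iter = 0; iter < 60; ++iter) {
      double sumP = 0, sumDP = 0;
      for (int j = 0; j < n; ++j) {
        if (j == i) { row[j] = 0; continue; }
        row[j] = std::exp(-beta * D2[(size_t)i * n + j]);
        sumP += row[j];
        sumDP += D2[(size_t)i * n + j] * row[j];
      }
      if (sumP <= 0) sumP = 1e-300;
      double H = std::log(sumP) + beta * sumDP / sumP;
      double diff = H - logU;
      if (std::fabs(diff) < 1e-5) break;
      if (diff > 0) {
        betamin = beta;
        beta = (betamax > 1e299) ? beta * 2 : (beta + betamax) / 2;
      } else {
        betamax = beta;
        beta = (betamin < -1e299) ? beta / 2 : (beta + betamin) / 2;
      }
    }
    double sumP = 0;
    for (int j = 0; j < n; ++j) sumP += row[j];
    if (sumP <= 0) sumP = 1e-300;
    for (int j = 0; j < n; ++j) P[(size_t)i * n + j] = row[j] / sumP;
  }
  // symmetrise and normalise
  double psum = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double v = (P[(size_t)i * n + j] + P[(size_t)j * n + i]);
      P[(size_t)i * n + j] = v;
      P[(size_t)j * n + i] = v;
      psum += 2 * v;
    }
  }
  for (size_t k = 0; k < P.size(); ++k) {
    P[k] = std::max(P[k] / psum, 1e-12);
  }
  for (int i = 0; i < n; ++i) P[(size_t)i * n + i] = 0;

  NumericMatrix Y = clone(Y0);
  std::vector<double> dY((size_t)n * 2), iY((size_t)n * 2, 0.0),
      gains((size_t)n * 2, 1.0), Q((size_t)n * n);
  const int stop_exag = 250;
  const double eta = 200.0;
  for (int iter = 0; iter < max_iter; ++iter) {
    double exag = (iter < stop_exag) ? 12.0 : 1.0;
    double momentum = (iter < 250) ? 0.5 : 0.8;
    double Z = 0;
    for (int i = 0; i < n; ++i) {
      Q[(size_t)i * n + i] = 0;
      for (int j = i + 1; j < n; ++j) {
        double dy0 = Y(i, 0) - Y(j, 0), dy1 = Y(i, 1) - Y(j, 1);
        double q = 1.0 / (1.0 + dy0 * dy0 + dy1 * dy1);
        Q[(size_t)i * n + j] = q;
        Q[(size_t)j * n + i] = q;
        Z += 2 * q;
      }
    }
    if (Z <= 0) Z = 1e-300;
    for (int i = 0; i < n; ++i) {
      double g0 = 0, g1 = 0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double q = Q[(size_t)i * n + j];
        double mult = (exag * P[(size_t)i * n + j] - q / Z) * q;
        g0 += mult * (Y(i, 0) - Y(j, 0));
        g1 += mult * (Y(i, 1) - Y(j, 1));
      }
      dY[(size_t)i * 2] = 4 * g0;
      dY[(size_t)i * 2 + 1] = 4 * g1;
    }
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < 2; ++k) {
        size_t id = (size_t)i * 2 + k;
        gains[id] = ((dY[id] > 0) != (iY[id] > 0)) ? gains[id] + 0.2
                                                   : gains[id] * 0.8;
        if (gains[id] < 0.01) gains[id] = 0.01;
        iY[id] = momentum * iY[id] - eta * gains[id] * dY[id];
        Y(i, k) += iY[id];
      }
    }
    // re-centre
    double m0 = 0, m1 = 0;
    for (int i = 0; i < n; ++i) { m0 += Y(i, 0); m1 += Y(i, 1); }
    m0 /= n; m1 /= n;
    for (int i = 0; i < n; ++i) { Y(i, 0) -= m0; Y(i, 1) -= m1; }
    if (iter % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return Y;
}
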