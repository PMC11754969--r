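#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exact tree-path Shapley attributions (path-dependent TreeSHAP) for binary
// trees with numeric splits routing x <= threshold to the left child. Trees
// arrive as parallel 0-based arrays with -1 marking absent children; `cover`
// holds the (weighted) number of training rows through each node and `value`
// the leaf output.

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

static void extend_path(PathElement *path, int depth, double zero_fraction,
                        double one_fraction, int feature_index) {
  path[depth].feature_index = feature_index;
  path[depth].zero_fraction = zero_fraction;
  path[depth].one_fraction = one_fraction;
  path[depth].pweight = depth == 0 ? 1.0 : 0.0;
  for (int i = depth - 1; i >= 0; --i) {
    path[i + 1].pweight += one_fraction * path[i].pweight * (i + 1) /
                           static_cast<double>(depth + 1);
    path[i].pweight = zero_fraction * path[i].pweight * (depth - i) /
                      static_cast<double>(depth + 1);
  }
}

static void unwind_path(PathElement *path, int depth, int index) {
  const double one_fraction = path[index].one_fraction;
  const double zero_fraction = path[index].zero_fraction;
  double next_one_portion = path[depth].pweight;
  for (int i = depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = path[i].pweight;
      path[i].pweight = next_one_portion * (depth + 1) /
                        static_cast<double>((i + 1) * one_fraction);
      next_one_portion = tmp - path[i].pweight * zero_fraction * (depth - i) /
                                   static_cast<double>(depth + 1);
    } else {
      path[i].pweight = (path[i].pweight * (depth + 1)) /
                        static_cast<double>(zero_fraction * (depth - i));
    }
  }
  for (int i = index; i < depth; ++i) {
    path[i].feature_index = path[i + 1].feature_index;
    path[i].zero_fraction = path[i + 1].zero_fraction;
    path[i].one_fraction = path[i + 1].one_fraction;
  }
}

static double unwound_path_sum(const PathElement *path, int depth, int index) {
  const double one_fraction = path[index].one_fraction;
  const double zero_fraction = path[index].zero_fraction;
  double next_one_portion = path[depth].pweight;
  double total = 0;
  for (int i = depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = next_one_portion * (depth + 1) /
                         static_cast<double>((i + 1) * one_fraction);
      total += tmp;
      next_one_portion = path[i].pweight -
                         tmp * zero_fraction * (depth - i) /
                             static_cast<double>(depth + 1);
    } else {
      total += (path[i].pweight / zero_fraction) /
               ((depth - i) / static_cast<double>(depth + 1));
    }
  }
  return total;
}

struct Tree {
  const int *left, *right, *feature;
  const double *threshold, *value, *cover;
};

static void shap_recurse(const Tree &tr, const double *x, double *phi,
                         int node, PathElement *parent_path, int depth,
                         double parent_zero, double parent_one,
                         int parent_feature) {
  PathElement *path = parent_path + depth + 1;
  std::copy(parent_path, parent_path + depth + 1, path);
  extend_path(path, depth, parent_zero, parent_one, parent_feature);

  if (tr.left[node] < 0) { // leaf
    for (int i = 1; i <= depth; ++i) {
      const double w = unwound_path_sum(path, depth, i);
      phi[path[i].feature_index] +=
          w * (path[i].one_fraction - path[i].zero_fraction) * tr.value[node];
    }
    return;
  }
  const int f = tr.feature[node];
  const int hot = (x[f] <= tr.threshold[node]) ? tr.left[node] : tr.right[node];
  const int cold = (hot == tr.left[node]) ? tr.right[node] : tr.left[node];
  const double hot_zero = tr.cover[hot] / tr.cover[node];
  const double cold_zero = tr.cover[cold] / tr.cover[node];
  double incoming_zero = 1.0, incoming_one = 1.0;
  int index = 0;
  for (; index <= depth; ++index) {
    if (path[index].feature_index == f) break;
  }
  if (index != depth + 1) {
    incoming_zero = path[index].zero_fraction;
    incoming_one = path[index].one_fraction;
    unwind_path(path, depth, index);
    depth -= 1;
  }
  shap_recurse(tr, x, phi, hot, path, depth + 1, hot_zero * incoming_zero,
               incoming_one, f);
  shap_recurse(tr, x, phi, cold, path, depth + 1, cold_zero * incoming_zero,
               0.0, f);
}

static Tree unpack_tree(const List &tree) {
  Tree tr;
  tr.left = INTEGER(((SEXP)tree["left"]));
  tr.right = INTEGER(((SEXP)tree["right"]));
  tr.feature = INTEGER(((SEXP)tree["feature"]));
  tr.threshold = REAL(((SEXP)tree["threshold"]));
  tr.value = REAL(((SEXP)tree["value"]));
  tr.cover = REAL(((SEXP)tree["cover"]));
  return tr;
}

static int tree_max_depth(const Tree &tr, int node) {
  if (tr.left[node] < 0) return 1;
  return 1 + std::max(tree_max_depth(tr, tr.left[node]),
                      tree_max_depth(tr, tr.right[node]));
}

// [[Rcpp::export(name = ".forest_shap")]]
List forest_shap(List trees, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol(), ntree = trees.size();
  NumericMatrix phi(n, p);
  double base = 0;
  std::vector<double> xrow(p);
  for (int t = 0; t < ntree; ++t) {
    Tree tr = unpack_tree(trees[t]);
    // expected value of the tree under its cover distribution
    int nnode = Rf_length(((SEXP)((List)trees[t])["left"]));
    double ev = 0;
    for (int j = 0; j < nnode; ++j) {
      if (tr.left[j] < 0) ev += tr.cover[j] / tr.cover[0] * tr.value[j];
    }
    base += ev / ntree;
    const int maxd = tree_max_depth(tr, 0) + 2;
    std::vector<PathElement> arena((size_t)(maxd + 1) * (maxd + 2) / 2 + maxd + 2);
    std::vector<double> phirow(p);
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < p; ++k) xrow[k] = X(i, k);
      std::fill(phirow.begin(), phirow.end(), 0.0);
      shap_recurse(tr, xrow.data(), phirow.data(), 0, arena.data(), 0, 1.0,
                   1.0, -1);
      for (int k = 0; k < p; ++k) phi(i, k) += phirow[k] / ntree;
    }
  }
  return List::create(_["phi"] = phi, _["base"] = base);
}

// Route rows through a tree, accumulating weighted cover per node and the
// weighted mean response per leaf. Used to reconstruct the inbag covers and
// leaf values of a fitted probability forest.
// [[Rcpp::export(name = ".tree_route")]]
List tree_route(IntegerVector left, IntegerVector right, IntegerVector feature,
                NumericVector threshold, NumericMatrix X, NumericVector y,
                NumericVector w) {
  const int nnode = left.size(), n = X.nrow();
  NumericVector cover(nnode), vsum(nnode), value(nnode);
  for (int i = 0; i < n; ++i) {
    if (w[i] <= 0) continue;
    int node = 0;
    for (;;) {
      cover[node] += w[i];
      if (left[node] < 0) { vsum[node] += w[i] * y[i]; break; }
      node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
    }
  }
  for (int j = 0; j < nnode; ++j) {
    value[j] = (left[j] < 0 && cover[j] > 0) ? vsum[j] / cover[j] : 0.0;
  }
  return List::create(_["cover"] = cover, _["value"] = value);
}
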