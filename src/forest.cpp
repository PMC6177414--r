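// Compact CART-style random forest for binary classification.
//
// Grown with Gini impurity, bootstrap resampling and mtry feature
// subsampling; leaves store class-1 proportions so predictions are
// probabilities (averaged over trees). Deterministic given `seed`.

#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>

using namespace Rcpp;

struct Tree {
  // node arrays; feature == -1 marks a leaf
  std::vector<int> feature;
  std::vector<double> threshold;
  std::vector<int> left;
  std::vector<int> right;
  std::vector<double> pred;
};

static int grow_node(const NumericMatrix &X, const IntegerVector &y,
                     std::vector<int> &idx, int lo, int hi, int depth,
                     int mtry, int min_node, int max_depth, std::mt19937 &rng,
                     Tree &tree) {
  int node = (int)tree.feature.size();
  tree.feature.push_back(-1);
  tree.threshold.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);
  int n = hi - lo, pos = 0;
  for (int i = lo; i < hi; ++i) pos += y[idx[i]];
  tree.pred.push_back(n > 0 ? (double)pos / n : 0.5);
  if (n < 2 * min_node || pos == 0 || pos == n || depth >= max_depth)
    return node;

  int p = X.ncol();
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  // partial Fisher-Yates to draw mtry candidate features
  int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) {
    std::uniform_int_distribution<int> d(j, p - 1);
    std::swap(feats[j], feats[d(rng)]);
  }

  double best_gain = 1e-12, parent_gini;
  double pp = (double)pos / n;
  parent_gini = 2.0 * pp * (1.0 - pp);
  int best_f = -1;
  double best_thr = 0.0;

  std::vector<int> ord(idx.begin() + lo, idx.begin() + hi);
  for (int fj = 0; fj < m; ++fj) {
    int f = feats[fj];
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return X(a, f) < X(b, f);
    });
    int lpos = 0;
    for (int i = 0; i < n - 1; ++i) {
      lpos += y[ord[i]];
      double xv = X(ord[i], f), xn = X(ord[i + 1], f);
      if (xn <= xv) continue;
      int nl = i + 1, nr = n - nl;
      if (nl < min_node || nr < min_node) continue;
      double pl = (double)lpos / nl, pr = (double)(pos - lpos) / nr;
      double child = ((double)nl / n) * 2.0 * pl * (1.0 - pl) +
                     ((double)nr / n) * 2.0 * pr * (1.0 - pr);
      double gain = parent_gini - child;
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (xv + xn);
      }
    }
  }
  if (best_f < 0) return node;

  // partition idx[lo:hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i) {
    if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
  }
  if (mid == lo || mid == hi) return node;
  tree.feature[node] = best_f;
  tree.threshold[node] = best_thr;
  int l = grow_node(X, y, idx, lo, mid, depth + 1, mtry, min_node, max_depth,
                    rng, tree);
  int r = grow_node(X, y, idx, mid, hi, depth + 1, mtry, min_node, max_depth,
                    rng, tree);
  tree.left[node] = l;
  tree.right[node] = r;
  return node;
}

// [[Rcpp::export(name = ".rf_fit")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                int min_node, int max_depth, int seed) {
  int n = X.nrow();
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> boot(0, n - 1);
  List trees(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    Tree tree;
    grow_node(X, y, idx, 0, n, 0, mtry, min_node, max_depth, rng, tree);
    trees[t] = List::create(
        _["feature"] = wrap(tree.feature), _["threshold"] = wrap(tree.threshold),
        _["left"] = wrap(tree.left), _["right"] = wrap(tree.right),
        _["pred"] = wrap(tree.pred));
  }
  return trees;
}

// [[Rcpp::export(name = ".rf_predict")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), ntree = trees.size();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericVector pred = tr["pred"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0) {
        node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                        : right[node];
      }
      out[i] += pred[node];
    }
  }
  return out / (double)ntree;
}
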