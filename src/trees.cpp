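// CART regression trees plus the two ensemble learners built on them:
// bagged random forests and squared-loss gradient boosting. Exact greedy
// split search (all cut points between distinct sorted values); at the row
// counts this package works with (hundreds of set-level records) histogram
// binning would buy nothing.
//
// All randomness (bootstrap resampling, feature subsampling) is drawn from
// R's RNG so that set.seed() in R makes fits bit-reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct TreeNode {
  int feature;      // -1 for leaf
  double threshold; // go left if x <= threshold
  int left, right;  // node indices, -1 for leaf
  double value;     // leaf prediction (node mean)
};

struct Builder {
  const NumericMatrix &X;
  const std::vector<double> &y;
  int max_depth;
  int min_leaf;
  int min_split;
  int mtry;
  std::vector<TreeNode> nodes;
  std::vector<int> feat_pool;

  Builder(const NumericMatrix &X_, const std::vector<double> &y_,
          int max_depth_, int min_leaf_, int min_split_, int mtry_)
      : X(X_), y(y_), max_depth(max_depth_), min_leaf(min_leaf_),
        min_split(min_split_), mtry(mtry_) {
    feat_pool.resize(X.ncol());
    for (int j = 0; j < X.ncol(); ++j) feat_pool[j] = j;
  }

  // Partial Fisher-Yates draw of `mtry` distinct features via R's RNG.
  void sample_features(std::vector<int> &out) {
    int p = (int)feat_pool.size();
    for (int i = 0; i < mtry; ++i) {
      int j = i + (int)(unif_rand() * (p - i));
      if (j >= p) j = p - 1;
      std::swap(feat_pool[i], feat_pool[j]);
    }
    out.assign(feat_pool.begin(), feat_pool.begin() + mtry);
  }

  int build(std::vector<int> &idx, int lo, int hi, int depth) {
    int n = hi - lo;
    double sum = 0.0;
    for (int i = lo; i < hi; ++i) sum += y[idx[i]];
    double mean = sum / n;

    int me = (int)nodes.size();
    nodes.push_back({-1, 0.0, -1, -1, mean});

    if (depth >= max_depth || n < min_split || n < 2 * min_leaf) return me;

    // purity check
    bool pure = true;
    for (int i = lo + 1; i < hi; ++i)
      if (y[idx[i]] != y[idx[lo]]) { pure = false; break; }
    if (pure) return me;

    std::vector<int> feats;
    sample_features(feats);

    double best_gain = 0.0;
    int best_feat = -1;
    double best_thr = 0.0;
    const double parent_score = sum * sum / n;

    std::vector<std::pair<double, double>> xy(n);
    for (int fi : feats) {
      for (int i = 0; i < n; ++i) {
        int r = idx[lo + i];
        xy[i] = {X(r, fi), y[r]};
      }
      std::sort(xy.begin(), xy.end());
      if (xy.front().first == xy.back().first) continue;
      double lsum = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        lsum += xy[i].second;
        if (xy[i].first == xy[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        double rsum = sum - lsum;
        double gain = lsum * lsum / nl + rsum * rsum / nr - parent_score;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_feat = fi;
          best_thr = 0.5 * (xy[i].first + xy[i + 1].first);
        }
      }
    }

    if (best_feat < 0) return me;

    // partition idx[lo..hi) in place
    int mid = lo;
    for (int i = lo; i < hi; ++i)
      if (X(idx[i], best_feat) <= best_thr) std::swap(idx[i], idx[mid++]);
    if (mid == lo || mid == hi) return me; // numeric degenerate

    nodes[me].feature = best_feat;
    nodes[me].threshold = best_thr;
    int l = build(idx, lo, mid, depth + 1);
    int r = build(idx, mid, hi, depth + 1);
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }
};

NumericMatrix pack(const std::vector<TreeNode> &nodes) {
  NumericMatrix m((int)nodes.size(), 5);
  for (size_t i = 0; i < nodes.size(); ++i) {
    m(i, 0) = nodes[i].feature;
    m(i, 1) = nodes[i].threshold;
    m(i, 2) = nodes[i].left;
    m(i, 3) = nodes[i].right;
    m(i, 4) = nodes[i].value;
  }
  return m;
}

double predict_one(const NumericMatrix &tree, const NumericMatrix &X, int row) {
  int node = 0;
  while ((int)tree(node, 0) >= 0) {
    int f = (int)tree(node, 0);
    node = (X(row, f) <= tree(node, 1)) ? (int)tree(node, 2) : (int)tree(node, 3);
  }
  return tree(node, 4);
}

NumericMatrix fit_tree(const NumericMatrix &X, const std::vector<double> &y,
                       const std::vector<int> &rows, int max_depth,
                       int min_leaf, int min_split, int mtry) {
  Builder b(X, y, max_depth, min_leaf, min_split, mtry);
  std::vector<int> idx(rows);
  b.nodes.reserve(2 * rows.size());
  b.build(idx, 0, (int)idx.size(), 0);
  return pack(b.nodes);
}

} // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                int max_depth, int min_leaf, bool bootstrap) {
  int n = X.nrow();
  std::vector<double> yv(y.begin(), y.end());
  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> rows(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) {
        int r = (int)(unif_rand() * n);
        if (r >= n) r = n - 1;
        rows[i] = r;
      }
    } else {
      for (int i = 0; i < n; ++i) rows[i] = i;
    }
    trees[t] = fit_tree(X, yv, rows, max_depth, min_leaf, 2, mtry);
  }
  return trees;
}

// [[Rcpp::export(name = ".ensemble_predict_cpp")]]
NumericVector ensemble_predict_cpp(List trees, NumericMatrix X, double scale,
                                   double offset) {
  int n = X.nrow(), nt = trees.size();
  NumericVector out(n, offset);
  for (int t = 0; t < nt; ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) out[i] += scale * predict_one(tree, X, i);
  }
  return out;
}

// [[Rcpp::export(name = ".gbr_fit_cpp")]]
List gbr_fit_cpp(NumericMatrix X, NumericVector y, int n_iter,
                 double learning_rate, int max_depth, int min_leaf) {
  int n = X.nrow();
  double f0 = 0.0;
  for (int i = 0; i < n; ++i) f0 += y[i];
  f0 /= n;

  std::vector<double> resid(n);
  for (int i = 0; i < n; ++i) resid[i] = y[i] - f0;

  std::vector<int> rows(n);
  for (int i = 0; i < n; ++i) rows[i] = i;

  List trees(n_iter);
  int mtry = X.ncol();
  for (int m = 0; m < n_iter; ++m) {
    NumericMatrix tree = fit_tree(X, resid, rows, max_depth, min_leaf, 2, mtry);
    for (int i = 0; i < n; ++i)
      resid[i] -= learning_rate * predict_one(tree, X, i);
    trees[m] = tree;
  }
  return List::create(Named("f0") = f0, Named("trees") = trees);
}
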