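#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

// Compact CART random forest for multi-class voxel classification.
// Bootstrap sampling per tree, Gini impurity splits over mtry random
// feature candidates, grown to purity (min_node = 1) by default. Forest
// probabilities are vote fractions over per-tree majority-leaf classes,
// matching a voting ensemble; argmax ties break toward the lower class.

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;
  std::vector<int> pred;         // majority class at leaf
};

static int majority_class(const std::vector<int>& counts) {
  int best = 0;
  for (size_t k = 1; k < counts.size(); ++k)
    if (counts[k] > counts[best]) best = (int)k;
  return best;
}

static void grow_node(const NumericMatrix& X, const IntegerVector& y,
                      int n_class, int mtry, int min_node, int max_depth,
                      std::vector<int>& idx, int depth, Tree& tree,
                      int node_id, std::mt19937& rng) {
  int n = (int)idx.size();
  std::vector<int> counts(n_class, 0);
  for (int i : idx) counts[y[i]]++;
  int maj = majority_class(counts);
  bool pure = counts[maj] == n;
  if (pure || n < 2 * min_node || n < 2 || depth >= max_depth) {
    tree.feature[node_id] = -1;
    tree.pred[node_id] = maj;
    return;
  }
  int p = X.ncol();
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  // partial Fisher-Yates to draw mtry candidates
  int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) {
    std::uniform_int_distribution<int> d(j, p - 1);
    std::swap(feats[j], feats[d(rng)]);
  }
  double best_gain = -1.0, best_thr = 0.0;
  int best_feat = -1;
  double n_d = (double)n;
  double parent_imp = 1.0;
  for (int k = 0; k < n_class; ++k) {
    double f = counts[k] / n_d;
    parent_imp -= f * f;
  }
  std::vector<std::pair<double, int>> vals(n);
  for (int j = 0; j < m; ++j) {
    int f = feats[j];
    for (int i = 0; i < n; ++i) vals[i] = {X(idx[i], f), y[idx[i]]};
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;
    std::vector<int> lc(n_class, 0), rc(counts);
    for (int i = 0; i < n - 1; ++i) {
      lc[vals[i].second]++;
      rc[vals[i].second]--;
      if (vals[i].first == vals[i + 1].first) continue;
      int nl = i + 1, nr = n - nl;
      if (nl < min_node || nr < min_node) continue;
      double li = 1.0, ri = 1.0;
      for (int k = 0; k < n_class; ++k) {
        double fl = lc[k] / (double)nl, fr = rc[k] / (double)nr;
        li -= fl * fl;
        ri -= fr * fr;
      }
      double gain = parent_imp - (nl * li + nr * ri) / n_d;
      if (gain > best_gain + 1e-15) {
        best_gain = gain;
        best_feat = f;
        best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best_feat < 0 || best_gain <= 1e-12) {
    tree.feature[node_id] = -1;
    tree.pred[node_id] = maj;
    return;
  }
  std::vector<int> lidx, ridx;
  for (int i : idx)
    (X(i, best_feat) <= best_thr ? lidx : ridx).push_back(i);
  if (lidx.empty() || ridx.empty()) {
    tree.feature[node_id] = -1;
    tree.pred[node_id] = maj;
    return;
  }
  tree.feature[node_id] = best_feat;
  tree.threshold[node_id] = best_thr;
  int lid = (int)tree.feature.size();
  tree.feature.push_back(0); tree.threshold.push_back(0.0);
  tree.left.push_back(-1); tree.right.push_back(-1); tree.pred.push_back(0);
  int rid = (int)tree.feature.size();
  tree.feature.push_back(0); tree.threshold.push_back(0.0);
  tree.left.push_back(-1); tree.right.push_back(-1); tree.pred.push_back(0);
  tree.left[node_id] = lid;
  tree.right[node_id] = rid;
  idx.clear(); idx.shrink_to_fit();
  grow_node(X, y, n_class, mtry, min_node, max_depth, lidx, depth + 1, tree,
            lid, rng);
  grow_node(X, y, n_class, mtry, min_node, max_depth, ridx, depth + 1, tree,
            rid, rng);
}

// [[Rcpp::export(name = ".rf_train_cpp")]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int n_class, int n_trees,
                  int mtry, int min_node, int max_depth, int seed) {
  int n = X.nrow();
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> boot(0, n - 1);
  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    Tree tree;
    tree.feature.assign(1, 0); tree.threshold.assign(1, 0.0);
    tree.left.assign(1, -1); tree.right.assign(1, -1); tree.pred.assign(1, 0);
    grow_node(X, y, n_class, mtry, min_node, max_depth, idx, 0, tree, 0, rng);
    trees[t] = List::create(_["feature"] = wrap(tree.feature),
                            _["threshold"] = wrap(tree.threshold),
                            _["left"] = wrap(tree.left),
                            _["right"] = wrap(tree.right),
                            _["pred"] = wrap(tree.pred));
  }
  return trees;
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericMatrix rf_predict_cpp(List trees, NumericMatrix X, int n_class) {
  int n = X.nrow();
  int n_trees = trees.size();
  NumericMatrix votes(n, n_class);
  for (int t = 0; t < n_trees; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"], pred = tr["pred"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = X(i, feature[node]) <= threshold[node] ? left[node] : right[node];
      votes(i, pred[node]) += 1.0;
    }
  }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < n_class; ++k) votes(i, k) /= n_trees;
  return votes;
}
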