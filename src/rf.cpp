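// Seeded random-forest classifier (bagged CART trees, Gini impurity,
// per-node feature subsampling).  Implemented here because no random-forest
// package is available in the target library; the contract is the standard
// one: bootstrap per tree, mtry features per split, majority vote with vote
// fractions as scores.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;   // -1 for leaf
  std::vector<double> thr;
  std::vector<int> left, right, leaf;
};

struct Builder {
  const NumericMatrix& X;
  const IntegerVector& y;     // 0-based classes
  int classes, mtry, min_node;
  std::mt19937& rng;
  Tree tree;

  Builder(const NumericMatrix& X_, const IntegerVector& y_, int classes_,
          int mtry_, int min_node_, std::mt19937& rng_)
    : X(X_), y(y_), classes(classes_), mtry(mtry_), min_node(min_node_),
      rng(rng_) {}

  int majority(const std::vector<int>& idx) {
    std::vector<int> cnt(classes, 0);
    for (int i : idx) ++cnt[y[i]];
    return (int)(std::max_element(cnt.begin(), cnt.end()) - cnt.begin());
  }

  double gini(const std::vector<int>& cnt, int n) {
    if (n == 0) return 0.0;
    double g = 1.0;
    for (int c : cnt) { const double p = (double)c / n; g -= p * p; }
    return g;
  }

  int grow(std::vector<int>& idx) {
    const int node = (int)tree.feature.size();
    tree.feature.push_back(-1);
    tree.thr.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.leaf.push_back(majority(idx));
    const int n = (int)idx.size();
    bool pure = true;
    for (int i : idx) if (y[i] != y[idx[0]]) { pure = false; break; }
    if (pure || n < std::max(2, min_node)) return node;

    // candidate features
    const int d = X.ncol();
    std::vector<int> feats(d);
    for (int f = 0; f < d; ++f) feats[f] = f;
    for (int f = 0; f < std::min(mtry, d); ++f) {
      std::uniform_int_distribution<int> u(f, d - 1);
      std::swap(feats[f], feats[u(rng)]);
    }
    double best_gain = 0.0, best_thr = 0.0;
    int best_f = -1;
    std::vector<int> cnt_all(classes, 0);
    for (int i : idx) ++cnt_all[y[i]];
    const double g0 = gini(cnt_all, n);
    std::vector<std::pair<double, int> > vals(n);
    for (int t = 0; t < std::min(mtry, d); ++t) {
      const int f = feats[t];
      for (int i = 0; i < n; ++i)
        vals[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
      std::sort(vals.begin(), vals.end());
      std::vector<int> cl(classes, 0);
      int nl = 0;
      for (int i = 0; i < n - 1; ++i) {
        ++cl[vals[i].second];
        ++nl;
        if (vals[i].first == vals[i + 1].first) continue;
        std::vector<int> cr(classes);
        for (int c = 0; c < classes; ++c) cr[c] = cnt_all[c] - cl[c];
        const int nr = n - nl;
        const double gain =
          g0 - ((double)nl / n) * gini(cl, nl) - ((double)nr / n) * gini(cr, nr);
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) return node;
    std::vector<int> li, ri;
    for (int i : idx) (X(i, best_f) <= best_thr ? li : ri).push_back(i);
    if (li.empty() || ri.empty()) return node;
    tree.feature[node] = best_f;
    tree.thr[node] = best_thr;
    const int ln = grow(li);
    tree.left[node] = ln;
    const int rn = grow(ri);
    tree.right[node] = rn;
    return node;
  }
};

int predict_tree(const List& tr, const NumericMatrix& X, int row) {
  IntegerVector feature = tr["feature"];
  NumericVector thr = tr["thr"];
  IntegerVector left = tr["left"], right = tr["right"], leaf = tr["leaf"];
  int node = 0;
  while (feature[node] >= 0)
    node = (X(row, feature[node]) <= thr[node]) ? left[node] : right[node];
  return leaf[node];
}

}  // namespace

// [[Rcpp::export]]
List cpp_rf_train(const NumericMatrix& X, const IntegerVector& y, int classes,
                  int n_trees, int mtry, int min_node, int seed) {
  std::mt19937 rng((unsigned)seed);
  const int n = X.nrow();
  List forest(n_trees);
  std::uniform_int_distribution<int> boot(0, n - 1);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    Builder b(X, y, classes, mtry, min_node, rng);
    b.grow(idx);
    forest[t] = List::create(
      _["feature"] = wrap(b.tree.feature), _["thr"] = wrap(b.tree.thr),
      _["left"] = wrap(b.tree.left), _["right"] = wrap(b.tree.right),
      _["leaf"] = wrap(b.tree.leaf));
    Rcpp::checkUserInterrupt();
  }
  return forest;
}

// [[Rcpp::export]]
NumericMatrix cpp_rf_predict(const List& forest, const NumericMatrix& X,
                             int classes) {
  const int n = X.nrow(), T = forest.size();
  NumericMatrix votes(n, classes);
  for (int t = 0; t < T; ++t) {
    List tr = forest[t];
    for (int i = 0; i < n; ++i) votes(i, predict_tree(tr, X, i)) += 1.0;
  }
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < classes; ++c) votes(i, c) /= T;
  return votes;
}
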