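// Random forest for binary classification: CART trees with weighted Gini
// impurity, bootstrap bagging, per-node feature subsampling (mtry), and
// impurity-decrease feature importances. Self-contained RNG (xorshift) so
// results are reproducible across platforms independent of R's RNG state.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  // uniform integer in [0, n)
  int unif_int(int n) { return (int)(next() % (uint64_t)n); }
};

struct Node {
  int feature;      // -1 for leaf
  double threshold; // goes left if x <= threshold
  int left, right;  // node indices
  double prob;      // weighted positive fraction (leaves)
};

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  const NumericVector& w;
  int mtry, max_depth, min_split;
  XRng& rng;
  std::vector<Node> nodes;
  std::vector<double>& importance;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, const NumericVector& w_,
              int mtry_, int max_depth_, int min_split_, XRng& rng_,
              std::vector<double>& imp)
    : X(X_), y(y_), w(w_), mtry(mtry_), max_depth(max_depth_),
      min_split(min_split_), rng(rng_), importance(imp) {}

  static double gini(double wpos, double wtot) {
    if (wtot <= 0) return 0.0;
    double p = wpos / wtot;
    return 2.0 * p * (1.0 - p);
  }

  int build(std::vector<int>& idx, int depth) {
    double wtot = 0, wpos = 0;
    for (int i : idx) { wtot += w[i]; wpos += w[i] * y[i]; }
    bool pure = (wpos <= 1e-12) || (wtot - wpos <= 1e-12);
    bool stop = pure || (int)idx.size() < min_split ||
                (max_depth > 0 && depth >= max_depth);
    int self = (int)nodes.size();
    nodes.push_back(Node{-1, 0.0, -1, -1, wtot > 0 ? wpos / wtot : 0.5});
    if (stop) return self;

    int p = X.ncol();
    double parent_imp = gini(wpos, wtot);
    double best_gain = 1e-12;
    int best_f = -1; double best_thr = 0;

    // sample mtry features without replacement
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    for (int j = 0; j < mtry && j < p; ++j)
      std::swap(feats[j], feats[j + rng.unif_int(p - j)]);

    std::vector<std::pair<double, int>> vals(idx.size());
    for (int jj = 0; jj < std::min(mtry, p); ++jj) {
      int f = feats[jj];
      for (size_t t = 0; t < idx.size(); ++t)
        vals[t] = {X(idx[t], f), idx[t]};
      std::sort(vals.begin(), vals.end());
      double lw = 0, lp = 0;
      for (size_t t = 0; t + 1 < vals.size(); ++t) {
        int i = vals[t].second;
        lw += w[i]; lp += w[i] * y[i];
        if (vals[t + 1].first <= vals[t].first) continue;  // no split between equal values
        double rw = wtot - lw, rp = wpos - lp;
        if (lw <= 0 || rw <= 0) continue;
        double child = (lw * gini(lp, lw) + rw * gini(rp, rw)) / wtot;
        double gain = parent_imp - child;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[t].first + vals[t + 1].first);
        }
      }
    }
    if (best_f < 0) return self;

    std::vector<int> lidx, ridx;
    for (int i : idx) (X(i, best_f) <= best_thr ? lidx : ridx).push_back(i);
    if (lidx.empty() || ridx.empty()) return self;
    importance[best_f] += best_gain * wtot;
    nodes[self].feature = best_f;
    nodes[self].threshold = best_thr;
    int l = build(lidx, depth + 1);
    nodes[self].left = l;
    int r = build(ridx, depth + 1);
    nodes[self].right = r;
    return self;
  }
};

double predict_tree(const NumericMatrix& nodes, const NumericMatrix& X, int row) {
  int at = 0;
  while (nodes(at, 0) >= 0) {
    int f = (int)nodes(at, 0);
    at = (X(row, f) <= nodes(at, 1)) ? (int)nodes(at, 2) : (int)nodes(at, 3);
  }
  return nodes(at, 4);
}

} // namespace

// [[Rcpp::export(name = ".rf_fit")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, NumericVector w,
                int ntree, int mtry, int max_depth, int min_split,
                double seed) {
  int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  std::vector<double> importance(p, 0.0);
  List trees(ntree);
  for (int t = 0; t < ntree; ++t) {
    XRng rng((uint64_t)seed * 2654435761ULL + 0x100000001b3ULL * (uint64_t)(t + 1));
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = rng.unif_int(n);   // bootstrap
    TreeBuilder tb(X, y, w, mtry, max_depth, min_split, rng, importance);
    tb.build(idx, 0);
    NumericMatrix nm((int)tb.nodes.size(), 5);
    for (size_t k = 0; k < tb.nodes.size(); ++k) {
      nm(k, 0) = tb.nodes[k].feature;
      nm(k, 1) = tb.nodes[k].threshold;
      nm(k, 2) = tb.nodes[k].left;
      nm(k, 3) = tb.nodes[k].right;
      nm(k, 4) = tb.nodes[k].prob;
    }
    trees[t] = nm;
  }
  double tot = 0;
  for (int j = 0; j < p; ++j) tot += importance[j];
  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = tot > 0 ? importance[j] / tot : 1.0 / p;
  return List::create(_["trees"] = trees, _["importance"] = imp);
}

// [[Rcpp::export(name = ".rf_predict")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    NumericMatrix nm = trees[t];
    for (int i = 0; i < n; ++i) out[i] += predict_tree(nm, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}
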