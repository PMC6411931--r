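#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include "rng.h"

using namespace Rcpp;

// A minimal deterministic classification random forest (CART + bagging):
// gini splits, mtry features sampled without replacement per node, trees
// grown to purity (nodesize 1), out-of-bag vote bookkeeping, permutation
// importance. Node tables are plain numeric matrices so fitted forests
// serialize to text.

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold; // go left if x <= threshold
  int left, right;  // child indices, -1 for leaf
  int pred;         // leaf class (0/1); majority for internal too
};

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int mtry, nodesize;
  XRng& rng;
  std::vector<Node> nodes;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_,
              int mtry_, int nodesize_, XRng& rng_)
      : X(X_), y(y_), mtry(mtry_), nodesize(nodesize_), rng(rng_) {}

  int build(std::vector<int>& idx) {
    int n = (int)idx.size();
    int n1 = 0;
    for (int i : idx) n1 += y[i];
    int n0 = n - n1;
    int node_id = (int)nodes.size();
    Node nd;
    nd.feature = -1; nd.threshold = 0.0; nd.left = -1; nd.right = -1;
    nd.pred = (n1 > n0) ? 1 : 0; // tie -> class 0, deterministic
    nodes.push_back(nd);

    if (n0 == 0 || n1 == 0 || n <= nodesize || n < 2) return node_id;

    int p = X.ncol();
    // sample mtry distinct features (partial Fisher-Yates)
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      int r = j + rng.unif_int(p - j);
      std::swap(feats[j], feats[r]);
    }

    double parent_imp = 2.0 * (double)n0 * (double)n1 / (double)n;
    double best_dec = 0.0;
    int best_f = -1;
    double best_thr = 0.0;

    std::vector<std::pair<double,int>> vals(n);
    for (int jj = 0; jj < m; ++jj) {
      int f = feats[jj];
      for (int i = 0; i < n; ++i) vals[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue; // constant
      int l1 = 0;
      for (int i = 0; i < n - 1; ++i) {
        l1 += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        int ln = i + 1, rn = n - ln;
        int l0 = ln - l1, r1 = n1 - l1, r0 = rn - r1;
        double child_imp = 2.0 * (double)l0 * (double)l1 / (double)ln
                         + 2.0 * (double)r0 * (double)r1 / (double)rn;
        double dec = parent_imp - child_imp;
        if (dec > best_dec + 1e-12) { // strict improvement, first wins ties
          best_dec = dec;
          best_f = f;
          best_thr = (vals[i].first + vals[i + 1].first) / 2.0;
        }
      }
    }

    if (best_f < 0) return node_id; // no useful split among sampled features

    std::vector<int> lidx, ridx;
    lidx.reserve(n); ridx.reserve(n);
    for (int i : idx) {
      if (X(i, best_f) <= best_thr) lidx.push_back(i); else ridx.push_back(i);
    }
    if (lidx.empty() || ridx.empty()) return node_id; // numeric degeneracy guard

    nodes[node_id].feature = best_f;
    nodes[node_id].threshold = best_thr;
    int l = build(lidx);
    int r = build(ridx);
    nodes[node_id].left = l;
    nodes[node_id].right = r;
    return node_id;
  }
};

int tree_predict_row(const NumericMatrix& tree, const NumericMatrix& X, int row,
                     const int* perm_map, int perm_feature) {
  int node = 0;
  for (;;) {
    int f = (int)tree(node, 0);
    if (f < 0) return (int)tree(node, 4);
    int src = row;
    if (perm_map != nullptr && f == perm_feature) src = perm_map[row];
    double v = X(src, f);
    node = (v <= tree(node, 1)) ? (int)tree(node, 2) : (int)tree(node, 3);
  }
}

NumericMatrix pack_tree(const std::vector<Node>& nodes) {
  NumericMatrix m((int)nodes.size(), 5);
  for (size_t i = 0; i < nodes.size(); ++i) {
    m(i, 0) = nodes[i].feature;
    m(i, 1) = nodes[i].threshold;
    m(i, 2) = nodes[i].left;
    m(i, 3) = nodes[i].right;
    m(i, 4) = nodes[i].pred;
  }
  colnames(m) = CharacterVector::create("feature", "threshold", "left", "right", "pred");
  return m;
}

} // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                int nodesize, double seed) {
  int n = X.nrow();
  List trees(n_trees);
  IntegerMatrix inbag(n, n_trees);
  IntegerVector oob_pos(n), oob_tot(n);

  for (int t = 0; t < n_trees; ++t) {
    // each tree has its own stream derived from (seed, t)
    XRng rng((uint64_t)seed * 0x100000001B3ULL + (uint64_t)(t + 1));
    std::vector<int> counts(n, 0);
    std::vector<int> idx;
    idx.reserve(n);
    for (int i = 0; i < n; ++i) {
      int r = rng.unif_int(n);
      counts[r]++;
    }
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < counts[i]; ++c) idx.push_back(i);

    TreeBuilder tb(X, y, mtry, nodesize, rng);
    tb.build(idx);
    NumericMatrix tree = pack_tree(tb.nodes);
    trees[t] = tree;
    for (int i = 0; i < n; ++i) {
      inbag(i, t) = counts[i];
      if (counts[i] == 0) {
        oob_tot[i]++;
        oob_pos[i] += tree_predict_row(tree, X, i, nullptr, -1);
      }
    }
  }

  return List::create(_["trees"] = trees, _["inbag"] = inbag,
                      _["oob_pos"] = oob_pos, _["oob_total"] = oob_tot);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), T = trees.size();
  NumericVector votes(n);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i)
      votes[i] += tree_predict_row(tree, X, i, nullptr, -1);
  }
  for (int i = 0; i < n; ++i) votes[i] /= (double)T;
  return votes;
}

// OOB permutation importance: mean decrease in OOB accuracy per feature.
// [[Rcpp::export(name = ".rf_importance_cpp")]]
NumericVector rf_importance_cpp(List trees, IntegerMatrix inbag,
                                NumericMatrix X, IntegerVector y, double seed) {
  int n = X.nrow(), p = X.ncol(), T = trees.size();
  NumericVector imp(p);
  std::vector<int> perm;
  for (int t = 0; t < T; ++t) {
    NumericMatrix tree = trees[t];
    std::vector<int> oob;
    for (int i = 0; i < n; ++i) if (inbag(i, t) == 0) oob.push_back(i);
    int m = (int)oob.size();
    if (m == 0) continue;
    int correct0 = 0;
    for (int i : oob) correct0 += (tree_predict_row(tree, X, i, nullptr, -1) == y[i]);
    double acc0 = (double)correct0 / m;
    for (int f = 0; f < p; ++f) {
      XRng rng((uint64_t)seed * 0x100000001B3ULL
               + (uint64_t)(t + 1) * 1000003ULL + (uint64_t)(f + 1));
      perm = oob;
      for (int i = m - 1; i > 0; --i) {
        int r = rng.unif_int(i + 1);
        std::swap(perm[i], perm[r]);
      }
      // perm_map maps row index -> row to read feature f from
      std::vector<int> perm_map(n);
      for (int i = 0; i < n; ++i) perm_map[i] = i;
      for (int i = 0; i < m; ++i) perm_map[oob[i]] = perm[i];
      int correct = 0;
      for (int i : oob)
        correct += (tree_predict_row(tree, X, i, perm_map.data(), f) == y[i]);
      imp[f] += acc0 - (double)correct / m;
    }
  }
  for (int f = 0; f < p; ++f) imp[f] /= (double)T;
  return imp;
}
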