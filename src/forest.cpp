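#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Random forest for two-class pair feature vectors.
//
// Trees are CART-style: Gini best split among `mtry` randomly chosen
// features, grown until leaves are pure, hold fewer than `min_split`
// instances, or no candidate feature admits an improving split.  All
// randomness is drawn from R's RNG (unif_rand), so results are fully
// determined by the R-side set.seed() call.
//
// A fitted tree is a numeric matrix with one row per node and columns
//   0 feature   1-based split feature index, 0 for a leaf
//   1 threshold split threshold (x <= thr goes left)
//   2 left      1-based row of left child, 0 for a leaf
//   3 right     1-based row of right child, 0 for a leaf
//   4 n0        class-0 bootstrap instances reaching the node
//   5 n1        class-1 bootstrap instances reaching the node
// The plain-matrix representation survives JSON round-trips unchanged.

namespace {

struct Node {
  int feature;      // 0-based, -1 for leaf
  double threshold;
  int left, right;  // 0-based row index, -1 for leaf
  int n0, n1;
};

inline int rand_int(int n) {
  // uniform on {0, ..., n-1} via R's RNG
  int k = static_cast<int>(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

inline double gini(double c0, double c1) {
  double n = c0 + c1;
  if (n <= 0.0) return 0.0;
  double p0 = c0 / n, p1 = c1 / n;
  return 1.0 - p0 * p0 - p1 * p1;
}

struct Grower {
  const NumericMatrix& X;
  const IntegerVector& y;
  int p;
  int mtry;
  int min_split;
  std::vector<Node> nodes;
  std::vector<double>& importance;  // accumulated weighted Gini decrease
  int n_root;
  std::vector<int> feat_pool;       // scratch for feature sampling

  Grower(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
         int min_split_, std::vector<double>& imp_)
      : X(X_), y(y_), p(X_.ncol()), mtry(mtry_), min_split(min_split_),
        importance(imp_), n_root(0), feat_pool(p) {}

  int grow(std::vector<int>& idx) {
    int n = static_cast<int>(idx.size());
    int c1 = 0;
    for (int i : idx) c1 += y[i];
    int c0 = n - c1;

    int me = static_cast<int>(nodes.size());
    nodes.push_back(Node{-1, 0.0, -1, -1, c0, c1});

    if (c0 == 0 || c1 == 0 || n < min_split) return me;

    // sample mtry distinct features (partial Fisher-Yates, order kept
    // for deterministic tie-breaking: first improving feature wins)
    for (int j = 0; j < p; ++j) feat_pool[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      int k = j + rand_int(p - j);
      std::swap(feat_pool[j], feat_pool[k]);
    }

    double parent_imp = gini(c0, c1);
    double best_gain = 0.0;
    int best_feat = -1;
    double best_thr = 0.0;

    std::vector<std::pair<double, int> > vals(n);
    for (int j = 0; j < m; ++j) {
      int f = feat_pool[j];
      for (int i = 0; i < n; ++i)
        vals[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
      std::sort(vals.begin(), vals.end());
      int l1 = 0;
      for (int i = 0; i < n - 1; ++i) {
        l1 += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        double child =
            (nl * gini(nl - l1, l1) + nr * gini(c0 - (nl - l1), c1 - l1)) / n;
        double gain = parent_imp - child;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_feat = f;
          best_thr = vals[i].first + (vals[i + 1].first - vals[i].first) / 2.0;
        }
      }
    }

    if (best_feat < 0) return me;  // no improving split among sampled features

    importance[best_feat] += (static_cast<double>(n) / n_root) * best_gain;

    std::vector<int> left_idx, right_idx;
    left_idx.reserve(n);
    right_idx.reserve(n);
    for (int i : idx) {
      if (X(i, best_feat) <= best_thr)
        left_idx.push_back(i);
      else
        right_idx.push_back(i);
    }
    // numerically a midpoint can coincide with the upper value; guard
    if (left_idx.empty() || right_idx.empty()) return me;

    nodes[me].feature = best_feat;
    nodes[me].threshold = best_thr;
    int l = grow(left_idx);
    nodes[me].left = l;
    int r = grow(right_idx);
    nodes[me].right = r;
    return me;
  }
};

NumericMatrix pack_tree(const std::vector<Node>& nodes) {
  int n = static_cast<int>(nodes.size());
  NumericMatrix out(n, 6);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = nodes[i].feature + 1;  // 1-based, 0 = leaf
    out(i, 1) = nodes[i].threshold;
    out(i, 2) = nodes[i].left + 1;
    out(i, 3) = nodes[i].right + 1;
    out(i, 4) = nodes[i].n0;
    out(i, 5) = nodes[i].n1;
  }
  colnames(out) =
      CharacterVector::create("feature", "threshold", "left", "right", "n0", "n1");
  return out;
}

inline int tree_vote(const NumericMatrix& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (tree(node, 0) > 0) {
    int f = static_cast<int>(tree(node, 0)) - 1;
    node = (X(row, f) <= tree(node, 1)) ? static_cast<int>(tree(node, 2)) - 1
                                        : static_cast<int>(tree(node, 3)) - 1;
  }
  // leaf majority; tie votes class 0
  return tree(node, 5) > tree(node, 4) ? 1 : 0;
}

}  // namespace

// [[Rcpp::export]]
List grow_forest_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                     int n_boot, int min_split) {
  int n = X.nrow(), p = X.ncol();
  if (n_boot <= 0) n_boot = n;
  List trees(n_trees);
  NumericVector importance(p);

  std::vector<double> imp_acc(p, 0.0);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n_boot);
    for (int i = 0; i < n_boot; ++i) idx[i] = rand_int(n);
    std::fill(imp_acc.begin(), imp_acc.end(), 0.0);
    Grower g(X, y, mtry, min_split, imp_acc);
    g.n_root = n_boot;
    g.nodes.reserve(2 * n_boot);
    g.grow(idx);
    trees[t] = pack_tree(g.nodes);
    for (int j = 0; j < p; ++j) importance[j] += imp_acc[j];
  }
  for (int j = 0; j < p; ++j) importance[j] /= n_trees;
  return List::create(_["trees"] = trees, _["importance"] = importance);
}

// [[Rcpp::export]]
NumericVector predict_forest_cpp(List trees, NumericMatrix X) {
  int n = X.nrow();
  int t = trees.size();
  NumericVector score(n);
  for (int k = 0; k < t; ++k) {
    NumericMatrix tree = trees[k];
    for (int i = 0; i < n; ++i) score[i] += tree_vote(tree, X, i);
  }
  for (int i = 0; i < n; ++i) score[i] /= t;
  return score;
}
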