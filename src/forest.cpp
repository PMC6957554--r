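#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Classification tree with cross-entropy (information) splits, grown on a
// bootstrap sample. Node encoding (one row per node):
//   col 0: feature index (0-based), -1 for a leaf
//   col 1: threshold (go left if x <= thr)
//   col 2: left child row (0-based), col 3: right child row
//   col 4: predicted class at a leaf (0/1)
//   col 5: node size, col 6: depth
// Feature subsets per split are drawn with R's RNG so trees are exactly
// reproducible from set.seed() on the R side. Leaf ties are broken by the
// label of the lowest-index sample in the leaf, which keeps the ensemble
// score antisymmetric under a global label swap.

static double entropy2(int n0, int n1) {
  int n = n0 + n1;
  if (n == 0 || n0 == 0 || n1 == 0) return 0.0;
  double p0 = (double)n0 / n, p1 = (double)n1 / n;
  return -(p0 * std::log(p0) + p1 * std::log(p1));
}

struct NodeTask {
  std::vector<int> rows;
  int depth;
  int self;
};

// [[Rcpp::export(name = ".grow_tree_cpp")]]
NumericMatrix grow_tree_cpp(NumericMatrix X, IntegerVector y,
                            IntegerVector rows, int mtry, int max_depth,
                            int min_leaf) {
  int p = X.ncol();
  std::vector<std::vector<double> > nodes;
  std::vector<NodeTask> stack;

  NodeTask root;
  root.rows.assign(rows.begin(), rows.end());
  root.depth = 0;
  root.self = 0;
  nodes.push_back(std::vector<double>(7, 0.0));
  stack.push_back(root);

  std::vector<int> feat_pool(p);

  while (!stack.empty()) {
    NodeTask task = stack.back();
    stack.pop_back();
    std::vector<int>& rws = task.rows;
    int n = rws.size();
    int n1 = 0;
    for (int i = 0; i < n; ++i) n1 += y[rws[i]];
    int n0 = n - n1;

    nodes[task.self][5] = n;
    nodes[task.self][6] = task.depth;

    bool make_leaf = (n0 == 0 || n1 == 0 || task.depth >= max_depth ||
                      n < 2 * min_leaf);
    int best_f = -1;
    double best_thr = 0.0, best_imp = entropy2(n0, n1) - 1e-12;

    if (!make_leaf) {
      // sample mtry distinct features (partial Fisher-Yates, R RNG)
      for (int j = 0; j < p; ++j) feat_pool[j] = j;
      int m = std::min(mtry, p);
      for (int j = 0; j < m; ++j) {
        int k = j + (int)std::floor(unif_rand() * (p - j));
        if (k >= p) k = p - 1;
        std::swap(feat_pool[j], feat_pool[k]);
      }
      std::vector<std::pair<double, int> > vals(n);
      for (int j = 0; j < m; ++j) {
        int f = feat_pool[j];
        for (int i = 0; i < n; ++i)
          vals[i] = std::make_pair(X(rws[i], f), y[rws[i]]);
        std::sort(vals.begin(), vals.end());
        int l1 = 0;
        for (int i = 0; i < n - 1; ++i) {
          l1 += vals[i].second;
          int nl = i + 1, nr = n - nl;
          if (vals[i].first == vals[i + 1].first) continue;
          if (nl < min_leaf || nr < min_leaf) continue;
          int l0 = nl - l1;
          double imp = (nl * entropy2(l0, l1) +
                        nr * entropy2(n1 - l1 >= 0 ? nr - (n1 - l1) : 0,
                                      n1 - l1)) / n;
          if (imp < best_imp) {
            best_imp = imp;
            best_f = f;
            best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
          }
        }
      }
      if (best_f < 0) make_leaf = true;
    }

    NodeTask left, right;
    if (!make_leaf) {
      left.depth = right.depth = task.depth + 1;
      for (int i = 0; i < n; ++i) {
        if (X(rws[i], best_f) <= best_thr) left.rows.push_back(rws[i]);
        else right.rows.push_back(rws[i]);
      }
      // the midpoint threshold of two adjacent doubles can round onto the
      // upper value, emptying one side; such a split is degenerate
      if (left.rows.empty() || right.rows.empty()) make_leaf = true;
    }

    if (make_leaf) {
      int pred;
      if (n1 > n0) pred = 1;
      else if (n0 > n1) pred = 0;
      else if (!rws.empty()) {
        int first = *std::min_element(rws.begin(), rws.end());
        pred = y[first];
      } else pred = 0;
      nodes[task.self][0] = -1;
      nodes[task.self][4] = pred;
      continue;
    }
    left.self = nodes.size();
    nodes.push_back(std::vector<double>(7, 0.0));
    right.self = nodes.size();
    nodes.push_back(std::vector<double>(7, 0.0));
    nodes[task.self][0] = best_f;
    nodes[task.self][1] = best_thr;
    nodes[task.self][2] = left.self;
    nodes[task.self][3] = right.self;
    stack.push_back(left);
    stack.push_back(right);
  }

  NumericMatrix out(nodes.size(), 7);
  for (size_t i = 0; i < nodes.size(); ++i)
    for (int j = 0; j < 7; ++j) out(i, j) = nodes[i][j];
  return out;
}

static int predict_one(const NumericMatrix& nodes, const NumericMatrix& X,
                       int row) {
  int cur = 0;
  while (nodes(cur, 0) >= 0) {
    int f = (int)nodes(cur, 0);
    cur = (X(row, f) <= nodes(cur, 1)) ? (int)nodes(cur, 2)
                                       : (int)nodes(cur, 3);
  }
  return (int)nodes(cur, 4);
}

// [[Rcpp::export(name = ".predict_tree_cpp")]]
IntegerVector predict_tree_cpp(NumericMatrix nodes, NumericMatrix X) {
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = predict_one(nodes, X, i);
  return out;
}

// Count of class-1 (malignant) votes per row across a list of trees.
// [[Rcpp::export(name = ".predict_forest_cpp")]]
IntegerVector predict_forest_cpp(List trees, NumericMatrix X) {
  int n = X.nrow();
  IntegerVector votes(n);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix nodes = trees[t];
    for (int i = 0; i < n; ++i) votes[i] += predict_one(nodes, X, i);
  }
  return votes;
}
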