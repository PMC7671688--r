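// Regression random forest (CART variance splitting, bootstrap bagging,
// per-node feature subsampling) with impurity-based feature importance
// ("mean decrease in variance"). Self-contained so the package has no
// run-time dependency on an external learner.

#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>

using namespace Rcpp;

struct Node {
  int feature;     // -1 for leaf
  double threshold;
  int left, right; // child node ids
  double value;    // leaf prediction
};

struct Tree {
  std::vector<Node> nodes;
};

static void build_node(const NumericMatrix &X, const NumericVector &y,
                       std::vector<int> &idx, int lo, int hi, int depth,
                       int mtry, int min_node, int max_depth,
                       std::mt19937 &rng, Tree &tree, int node_id,
                       std::vector<double> &importance) {
  const int n = hi - lo;
  double sum = 0.0, sum2 = 0.0;
  for (int t = lo; t < hi; ++t) {
    double v = y[idx[t]];
    sum += v; sum2 += v * v;
  }
  const double mean = sum / n;
  const double ss_parent = sum2 - sum * sum / n;

  tree.nodes[node_id].feature = -1;
  tree.nodes[node_id].value = mean;
  if (n < 2 * min_node || depth >= max_depth || ss_parent <= 1e-12) return;

  const int p = X.ncol();
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  std::shuffle(feats.begin(), feats.end(), rng);

  double best_gain = 1e-12;
  int best_f = -1, best_pos = -1;
  double best_thr = 0.0;
  std::vector<int> order(n), best_order;

  for (int fi = 0; fi < std::min(mtry, p); ++fi) {
    const int f = feats[fi];
    for (int t = 0; t < n; ++t) order[t] = idx[lo + t];
    std::sort(order.begin(), order.end(), [&](int a, int b) {
      return X(a, f) < X(b, f);
    });
    double lsum = 0.0, lsum2 = 0.0;
    for (int t = 0; t < n - 1; ++t) {
      const double v = y[order[t]];
      lsum += v; lsum2 += v * v;
      const int nl = t + 1, nr = n - nl;
      if (nl < min_node || nr < min_node) continue;
      if (X(order[t], f) == X(order[t + 1], f)) continue;
      const double rsum = sum - lsum, rsum2 = sum2 - lsum2;
      const double ss_l = lsum2 - lsum * lsum / nl;
      const double ss_r = rsum2 - rsum * rsum / nr;
      const double gain = ss_parent - ss_l - ss_r;
      if (gain > best_gain) {
        best_gain = gain; best_f = f; best_pos = nl;
        best_thr = 0.5 * (X(order[t], f) + X(order[t + 1], f));
        best_order = order;
      }
    }
  }
  if (best_f < 0) return;

  importance[best_f] += best_gain;
  // partition idx[lo..hi) by the stored order
  for (int t = 0; t < n; ++t) idx[lo + t] = best_order[t];
  const int mid = lo + best_pos;

  const int left_id = (int)tree.nodes.size();
  tree.nodes.push_back(Node{-1, 0.0, -1, -1, 0.0});
  const int right_id = (int)tree.nodes.size();
  tree.nodes.push_back(Node{-1, 0.0, -1, -1, 0.0});
  tree.nodes[node_id].feature = best_f;
  tree.nodes[node_id].threshold = best_thr;
  tree.nodes[node_id].left = left_id;
  tree.nodes[node_id].right = right_id;

  build_node(X, y, idx, lo, mid, depth + 1, mtry, min_node, max_depth, rng,
             tree, left_id, importance);
  build_node(X, y, idx, mid, hi, depth + 1, mtry, min_node, max_depth, rng,
             tree, right_id, importance);
}

static double predict_one(const Tree &tree, const NumericMatrix &X, int row) {
  int id = 0;
  while (tree.nodes[id].feature >= 0) {
    id = (X(row, tree.nodes[id].feature) <= tree.nodes[id].threshold)
             ? tree.nodes[id].left
             : tree.nodes[id].right;
  }
  return tree.nodes[id].value;
}

// [[Rcpp::export(name = ".rf_train")]]
List rf_train_cpp(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                  int min_node, int max_depth, int seed) {
  const int n = X.nrow(), p = X.ncol();
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> boot(0, n - 1);
  std::vector<Tree> forest(n_trees);
  std::vector<double> importance(p, 0.0);
  for (int b = 0; b < n_trees; ++b) {
    std::vector<int> idx(n);
    for (int t = 0; t < n; ++t) idx[t] = boot(rng);
    forest[b].nodes.push_back(Node{-1, 0.0, -1, -1, 0.0});
    build_node(X, y, idx, 0, n, 0, mtry, min_node, max_depth, rng, forest[b],
               0, importance);
  }
  double tot = 0.0;
  for (int j = 0; j < p; ++j) tot += importance[j];
  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = tot > 0 ? importance[j] / tot : 0.0;

  // serialise forest as a list of matrices (feature, threshold, l, r, value)
  List trees(n_trees);
  for (int b = 0; b < n_trees; ++b) {
    const int m = (int)forest[b].nodes.size();
    NumericMatrix tm(m, 5);
    for (int i = 0; i < m; ++i) {
      tm(i, 0) = forest[b].nodes[i].feature;
      tm(i, 1) = forest[b].nodes[i].threshold;
      tm(i, 2) = forest[b].nodes[i].left;
      tm(i, 3) = forest[b].nodes[i].right;
      tm(i, 4) = forest[b].nodes[i].value;
    }
    trees[b] = tm;
  }
  return List::create(_["trees"] = trees, _["importance"] = imp);
}

// [[Rcpp::export(name = ".rf_predict")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow();
  const int B = trees.size();
  NumericVector out(n);
  for (int b = 0; b < B; ++b) {
    NumericMatrix tm = trees[b];
    Tree tr;
    tr.nodes.resize(tm.nrow());
    for (int i = 0; i < tm.nrow(); ++i) {
      tr.nodes[i] = Node{(int)tm(i, 0), tm(i, 1), (int)tm(i, 2), (int)tm(i, 3),
                         tm(i, 4)};
    }
    for (int r = 0; r < n; ++r) out[r] += predict_one(tr, X, r);
  }
  return out / (double)B;
}
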