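#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Depth-limited weighted regression tree grown by exhaustive search over
// axis-aligned splits minimising weighted squared error. Importance is the
// per-feature sum of weighted-MSE decreases (SSE decrease / total root
// weight), the bookkeeping needed for ensemble importance scores.

struct Node {
  int feature;      // -1 for leaf
  double threshold; // midpoint split: x < threshold goes left
  double value;     // weighted mean of node
  int left, right;  // child indices, -1 for leaf
};

struct Grower {
  const NumericMatrix& X;
  const NumericVector& y;
  const NumericVector& w;
  int max_depth, min_leaf;
  double w_root;
  std::vector<Node> nodes;
  std::vector<double> importance;
  int n_branch;

  Grower(const NumericMatrix& X_, const NumericVector& y_,
         const NumericVector& w_, int max_depth_, int min_leaf_)
    : X(X_), y(y_), w(w_), max_depth(max_depth_), min_leaf(min_leaf_),
      importance(X_.ncol(), 0.0), n_branch(0) {
    w_root = 0.0;
    for (int i = 0; i < w.size(); ++i) w_root += w[i];
  }

  // weighted SSE of subset about its weighted mean
  static void moments(const NumericVector& y, const NumericVector& w,
                      const std::vector<int>& idx,
                      double& W, double& mean, double& sse) {
    W = 0.0; double S = 0.0;
    for (int i : idx) { W += w[i]; S += w[i] * y[i]; }
    mean = (W > 0.0) ? S / W : 0.0;
    sse = 0.0;
    for (int i : idx) { double d = y[i] - mean; sse += w[i] * d * d; }
  }

  int grow(std::vector<int>& idx, int depth) {
    double W, mean, sse;
    moments(y, w, idx, W, mean, sse);
    int me = (int)nodes.size();
    nodes.push_back(Node{-1, 0.0, mean, -1, -1});
    int n = (int)idx.size();
    if (depth >= max_depth || n < 2 * min_leaf || sse <= 1e-12) return me;

    int p = X.ncol();
    int best_f = -1; double best_gain = 0.0, best_thr = 0.0;
    std::vector<int> ord(idx);
    for (int j = 0; j < p; ++j) {
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        double xa = X(a, j), xb = X(b, j);
        if (xa != xb) return xa < xb;
        return a < b;
      });
      // cumulative weighted sums from the left
      double wl = 0.0, sl = 0.0, ql = 0.0;
      double wt = 0.0, st = 0.0, qt = 0.0;
      for (int k = 0; k < n; ++k) {
        int i = ord[k]; wt += w[i]; st += w[i] * y[i]; qt += w[i] * y[i] * y[i];
      }
      double sse_parent = qt - (wt > 0 ? st * st / wt : 0.0);
      for (int k = 0; k < n - 1; ++k) {
        int i = ord[k];
        wl += w[i]; sl += w[i] * y[i]; ql += w[i] * y[i] * y[i];
        double xk = X(i, j), xn = X(ord[k + 1], j);
        if (xk == xn) continue;              // not a boundary between values
        if (k + 1 < min_leaf || n - k - 1 < min_leaf) continue;
        double wr = wt - wl, sr = st - sl;
        if (wl <= 0.0 || wr <= 0.0) continue;
        double sse_l = ql - sl * sl / wl;
        double sse_r = (qt - ql) - sr * sr / wr;
        double gain = sse_parent - sse_l - sse_r;
        if (gain > best_gain + 1e-12) {
          best_gain = gain; best_f = j; best_thr = 0.5 * (xk + xn);
        }
      }
    }
    if (best_f < 0) return me;

    std::vector<int> lidx, ridx;
    for (int i : idx) (X(i, best_f) < best_thr ? lidx : ridx).push_back(i);
    if (lidx.empty() || ridx.empty()) return me;

    nodes[me].feature = best_f;
    nodes[me].threshold = best_thr;
    importance[best_f] += best_gain / w_root;  // decrease in weighted MSE
    ++n_branch;
    int l = grow(lidx, depth + 1);
    int r = grow(ridx, depth + 1);
    nodes[me].left = l; nodes[me].right = r;
    return me;
  }
};

// [[Rcpp::export(name = ".tree_fit_cpp")]]
List tree_fit_cpp(NumericMatrix X, NumericVector y, NumericVector w,
                  int max_depth, int min_leaf) {
  int n = X.nrow();
  if (y.size() != n || w.size() != n) stop("X, y, w size mismatch");
  Grower g(X, y, w, max_depth, min_leaf);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  g.grow(idx, 0);

  int m = (int)g.nodes.size();
  IntegerVector feature(m), left(m), right(m);
  NumericVector threshold(m), value(m);
  for (int k = 0; k < m; ++k) {
    feature[k] = g.nodes[k].feature;  // 0-based, -1 leaf
    threshold[k] = g.nodes[k].threshold;
    value[k] = g.nodes[k].value;
    left[k] = g.nodes[k].left;
    right[k] = g.nodes[k].right;
  }
  return List::create(
    _["feature"] = feature, _["threshold"] = threshold, _["value"] = value,
    _["left"] = left, _["right"] = right,
    _["importance"] = NumericVector(g.importance.begin(), g.importance.end()),
    _["n_branch"] = g.n_branch);
}

// [[Rcpp::export(name = ".tree_predict_cpp")]]
NumericVector tree_predict_cpp(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int k = 0;
    while (feature[k] >= 0)
      k = (X(i, feature[k]) < threshold[k]) ? left[k] : right[k];
    out[i] = value[k];
  }
  return out;
}
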