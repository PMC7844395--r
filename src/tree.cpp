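#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// binary classification entropy in bits
static double entropy2(double n0, double n1) {
  double n = n0 + n1;
  double h = 0.0;
  if (n0 > 0) { double p = n0 / n; h -= p * std::log2(p); }
  if (n1 > 0) { double p = n1 / n; h -= p * std::log2(p); }
  return h;
}

struct Node {
  int feature;      // 1-based column of X, 0 for leaf
  double threshold; // x <= threshold goes left
  double gain;      // information gain in bits
  int n;            // samples reaching the node
  int left, right;  // 1-based node ids, 0 for none
  int pred;         // majority class (ties -> 0)
};

// Greedy unpruned entropy-gain tree with midpoint thresholds.
// Stopping: pure node, fewer than 2*min_leaf samples, or no split with
// positive gain leaving >= min_leaf samples on each side. Ties between
// candidate splits are broken by lowest feature index, then lowest
// threshold (enforced by ascending scan order and a strict-improvement
// tolerance of 1e-12 bits).
// [[Rcpp::export(name = ".build_tree_cpp")]]
List build_tree_cpp(NumericMatrix X, IntegerVector y, int min_leaf) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 1 || p < 1) stop("empty input");
  std::vector<Node> nodes;
  // work stack: (node id, sample indices)
  std::vector<std::pair<int, std::vector<int> > > stack;
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  nodes.push_back(Node());
  stack.push_back(std::make_pair(0, all));

  std::vector<std::pair<double, int> > vals;
  while (!stack.empty()) {
    int id = stack.back().first;
    std::vector<int> idx = stack.back().second;
    stack.pop_back();
    const int m = (int)idx.size();
    int c1 = 0;
    for (int i = 0; i < m; ++i) c1 += y[idx[i]];
    int c0 = m - c1;
    Node nd;
    nd.feature = 0; nd.threshold = NA_REAL; nd.gain = 0.0;
    nd.n = m; nd.left = 0; nd.right = 0;
    nd.pred = (c1 > c0) ? 1 : 0;
    double h_parent = entropy2(c0, c1);
    bool stop_node = (c0 == 0 || c1 == 0 || m < 2 * min_leaf);
    int best_f = -1, best_nl = 0;
    double best_gain = 0.0, best_thr = 0.0;
    if (!stop_node) {
      for (int j = 0; j < p; ++j) {
        vals.clear();
        for (int i = 0; i < m; ++i)
          vals.push_back(std::make_pair(X(idx[i], j), y[idx[i]]));
        std::sort(vals.begin(), vals.end());
        int left1 = 0;
        for (int i = 0; i < m - 1; ++i) {
          left1 += vals[i].second;
          if (vals[i].first == vals[i + 1].first) continue;
          int nl = i + 1, nr = m - nl;
          if (nl < min_leaf || nr < min_leaf) continue;
          double gain = h_parent -
            ((double)nl / m) * entropy2(nl - left1, left1) -
            ((double)nr / m) * entropy2(m - c1 - (nl - left1), c1 - left1);
          if (gain > best_gain + 1e-12) {
            best_gain = gain;
            best_f = j;
            best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
            best_nl = nl;
          }
        }
      }
    }
    if (best_f >= 0 && best_gain > 1e-12) {
      nd.feature = best_f + 1;
      nd.threshold = best_thr;
      nd.gain = best_gain;
      std::vector<int> lidx, ridx;
      lidx.reserve(best_nl); ridx.reserve(m - best_nl);
      for (int i = 0; i < m; ++i) {
        if (X(idx[i], best_f) <= best_thr) lidx.push_back(idx[i]);
        else ridx.push_back(idx[i]);
      }
      int lid = (int)nodes.size(); nodes.push_back(Node());
      int rid = (int)nodes.size(); nodes.push_back(Node());
      nd.left = lid + 1; nd.right = rid + 1;
      stack.push_back(std::make_pair(lid, lidx));
      stack.push_back(std::make_pair(rid, ridx));
    }
    nodes[id] = nd;
  }
  const int nn = (int)nodes.size();
  IntegerVector feature(nn), nsamp(nn), left(nn), right(nn), pred(nn);
  NumericVector threshold(nn), gain(nn);
  for (int i = 0; i < nn; ++i) {
    feature[i] = nodes[i].feature; threshold[i] = nodes[i].threshold;
    gain[i] = nodes[i].gain; nsamp[i] = nodes[i].n;
    left[i] = nodes[i].left; right[i] = nodes[i].right;
    pred[i] = nodes[i].pred;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["gain"] = gain, _["n"] = nsamp, _["left"] = left,
                      _["right"] = right, _["pred"] = pred);
}

// [[Rcpp::export(name = ".predict_tree_cpp")]]
IntegerVector predict_tree_cpp(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
    right = tree["right"], pred = tree["pred"];
  NumericVector threshold = tree["threshold"];
  const int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int cur = 0;
    while (feature[cur] != 0) {
      cur = (X(i, feature[cur] - 1) <= threshold[cur]) ?
        left[cur] - 1 : right[cur] - 1;
    }
    out[i] = pred[cur];
  }
  return out;
}
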