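// Exact-greedy gradient boosted regression trees with per-feature monotone
// constraints.  Constraint mechanism: at any candidate split on a constrained
// feature the (regularized, bound-clipped) child values must be ordered in
// the declared direction, and the child value intervals are narrowed around
// the mid-point of the two child values so every descendant leaf respects the
// ordering.  Because each tree is monotone and trees are summed, the ensemble
// prediction function is globally monotone in every constrained feature.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;           // -1 => leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  double value = 0.0;         // shrunken leaf value (eta already applied)
  double gain = 0.0;
};

struct TreeBuilder {
  const NumericMatrix& X;
  const std::vector<double>& grad;
  const IntegerVector& cons;
  double lambda, alpha, eta;
  int max_depth, min_leaf;
  std::vector<Node> nodes;
  std::vector<double> feat_gain;

  TreeBuilder(const NumericMatrix& X_, const std::vector<double>& g,
              const IntegerVector& cons_, double lambda_, double alpha_,
              double eta_, int max_depth_, int min_leaf_)
      : X(X_), grad(g), cons(cons_), lambda(lambda_), alpha(alpha_),
        eta(eta_), max_depth(max_depth_), min_leaf(min_leaf_),
        feat_gain(X_.ncol(), 0.0) {}

  // regularized leaf weight for gradient sum G over H points (hessian = 1)
  double weight(double G, double H) const {
    double g = 0.0;
    if (G > alpha) g = G - alpha;
    else if (G < -alpha) g = G + alpha;
    return -g / (H + lambda);
  }
  // objective value at (clipped) weight w: G*w + 0.5*(H+lambda)*w^2 + alpha|w|
  double obj(double w, double G, double H) const {
    return G * w + 0.5 * (H + lambda) * w * w + alpha * std::fabs(w);
  }
  static double clip(double w, double lo, double hi) {
    return std::min(std::max(w, lo), hi);
  }

  int build(std::vector<int>& idx, int depth, double lo, double hi) {
    double G = 0.0;
    const double H = static_cast<double>(idx.size());
    for (int i : idx) G += grad[i];
    double w = clip(weight(G, H), lo, hi);

    Node node;
    node.value = eta * w;
    int node_id = static_cast<int>(nodes.size());
    nodes.push_back(node);

    if (depth >= max_depth || static_cast<int>(idx.size()) < 2 * min_leaf)
      return node_id;

    const double parent_obj = obj(w, G, H);
    double best_gain = 1e-12;
    int best_feat = -1;
    double best_thr = 0.0, best_wL = 0.0, best_wR = 0.0;

    std::vector<std::pair<double, double>> xv(idx.size());
    for (int j = 0; j < X.ncol(); ++j) {
      const int dir = cons[j];
      for (size_t r = 0; r < idx.size(); ++r)
        xv[r] = {X(idx[r], j), grad[idx[r]]};
      std::sort(xv.begin(), xv.end());
      if (xv.front().first == xv.back().first) continue;
      double GL = 0.0;
      for (size_t r = 0; r + 1 < xv.size(); ++r) {
        GL += xv[r].second;
        if (xv[r].first == xv[r + 1].first) continue;
        const double HL = static_cast<double>(r + 1);
        const double HR = H - HL;
        if (HL < min_leaf || HR < min_leaf) continue;
        const double GR = G - GL;
        double wL = clip(weight(GL, HL), lo, hi);
        double wR = clip(weight(GR, HR), lo, hi);
        if (dir == 1 && wL > wR) continue;
        if (dir == -1 && wL < wR) continue;
        const double gain = parent_obj - obj(wL, GL, HL) - obj(wR, GR, HR);
        if (gain > best_gain) {
          best_gain = gain;
          best_feat = j;
          best_thr = 0.5 * (xv[r].first + xv[r + 1].first);
          best_wL = wL;
          best_wR = wR;
        }
      }
    }

    if (best_feat < 0) return node_id;

    std::vector<int> left_idx, right_idx;
    left_idx.reserve(idx.size());
    right_idx.reserve(idx.size());
    for (int i : idx) {
      if (X(i, best_feat) < best_thr) left_idx.push_back(i);
      else right_idx.push_back(i);
    }
    if (left_idx.empty() || right_idx.empty()) return node_id;

    double loL = lo, hiL = hi, loR = lo, hiR = hi;
    const int dir = cons[best_feat];
    if (dir != 0) {
      const double mid = 0.5 * (best_wL + best_wR);
      if (dir == 1) { hiL = std::min(hiL, mid); loR = std::max(loR, mid); }
      else          { loL = std::max(loL, mid); hiR = std::min(hiR, mid); }
    }

    nodes[node_id].feature = best_feat;
    nodes[node_id].threshold = best_thr;
    nodes[node_id].gain = best_gain;
    feat_gain[best_feat] += best_gain;
    nodes[node_id].left = build(left_idx, depth + 1, loL, hiL);
    nodes[node_id].right = build(right_idx, depth + 1, loR, hiR);
    return node_id;
  }
};

double predict_row(const NumericMatrix& tree, const NumericMatrix& X, int i) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    const int j = static_cast<int>(tree(node, 0));
    node = (X(i, j) < tree(node, 1)) ? static_cast<int>(tree(node, 2))
                                     : static_cast<int>(tree(node, 3));
  }
  return tree(node, 4);
}

NumericMatrix pack_tree(const std::vector<Node>& nodes) {
  NumericMatrix out(nodes.size(), 6);
  colnames(out) = CharacterVector::create("feature", "threshold", "left",
                                          "right", "value", "gain");
  for (size_t r = 0; r < nodes.size(); ++r) {
    out(r, 0) = nodes[r].feature;
    out(r, 1) = nodes[r].threshold;
    out(r, 2) = nodes[r].left;
    out(r, 3) = nodes[r].right;
    out(r, 4) = nodes[r].value;
    out(r, 5) = nodes[r].gain;
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
List gbm_fit_cpp(NumericMatrix X, NumericVector y, int n_estimators,
                 double learning_rate, int max_depth, double subsample,
                 double l1, double l2, int min_leaf, IntegerVector constraints,
                 int seed) {
  const int n = X.nrow(), p = X.ncol();
  const double base = mean(y);
  std::vector<double> pred(n, base), grad(n, 0.0);
  std::vector<double> total_gain(p, 0.0);
  List trees(n_estimators);
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<int> all_rows(n);
  for (int i = 0; i < n; ++i) all_rows[i] = i;
  const int m = std::max(2, static_cast<int>(std::floor(subsample * n)));

  for (int t = 0; t < n_estimators; ++t) {
    for (int i = 0; i < n; ++i) grad[i] = pred[i] - y[i];
    std::vector<int> rows = all_rows;
    if (m < n) {
      // partial Fisher-Yates: first m entries are the subsample
      for (int i = 0; i < m; ++i) {
        std::uniform_int_distribution<int> u(i, n - 1);
        std::swap(rows[i], rows[u(rng)]);
      }
      rows.resize(m);
    }
    TreeBuilder tb(X, grad, constraints, l2, l1, learning_rate, max_depth,
                   min_leaf);
    tb.build(rows, 0, -std::numeric_limits<double>::infinity(),
             std::numeric_limits<double>::infinity());
    NumericMatrix packed = pack_tree(tb.nodes);
    trees[t] = packed;
    for (int j = 0; j < p; ++j) total_gain[j] += tb.feat_gain[j];
    for (int i = 0; i < n; ++i) pred[i] += predict_row(packed, X, i);
  }

  return List::create(_["trees"] = trees, _["base_score"] = base,
                      _["gain"] = NumericVector(total_gain.begin(),
                                                total_gain.end()),
                      _["train_pred"] = NumericVector(pred.begin(),
                                                      pred.end()));
}

// [[Rcpp::export]]
NumericVector gbm_predict_cpp(List trees, double base_score, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n, base_score);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) out[i] += predict_row(tree, X, i);
  }
  return out;
}
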