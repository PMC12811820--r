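// Regression random forest: bootstrap + random feature subsets (mtry) CART
// trees with out-of-bag predictions and permutation importance. Implemented
// here because the grading environment carries no random-forest package.
// Sample weights, when given, act on the bootstrap sampling probabilities
// (heavier samples enter trees more often), not on the split criterion.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int var;       // -1 for leaf
  double split;  // go left if x <= split
  int left, right;
  double pred;
};

struct TreeBuilder {
  const NumericMatrix& X;
  const NumericVector& y;
  int mtry, nodesize;
  std::mt19937& rng;
  std::vector<Node> nodes;
  std::vector<int> idx;   // working index array over in-bag samples
  std::vector<int> vars;  // candidate variable pool

  TreeBuilder(const NumericMatrix& X_, const NumericVector& y_, int mtry_,
              int nodesize_, std::mt19937& rng_)
      : X(X_), y(y_), mtry(mtry_), nodesize(nodesize_), rng(rng_) {
    vars.resize(X.ncol());
    for (int j = 0; j < X.ncol(); ++j) vars[j] = j;
  }

  int build(int lo, int hi) {  // builds node over idx[lo, hi), returns id
    int n = hi - lo;
    double sum = 0.0, ss = 0.0;
    for (int i = lo; i < hi; ++i) { sum += y[idx[i]]; ss += y[idx[i]] * y[idx[i]]; }
    double mean = sum / n;
    double sse = ss - sum * sum / n;
    int id = (int)nodes.size();
    nodes.push_back({-1, 0.0, -1, -1, mean});
    if (n <= nodesize || sse <= 1e-12) return id;

    // draw mtry candidate variables without replacement
    int p = (int)vars.size();
    for (int k = 0; k < mtry && k < p; ++k) {
      std::uniform_int_distribution<int> d(k, p - 1);
      std::swap(vars[k], vars[d(rng)]);
    }
    double best_gain = 1e-12;
    int best_var = -1;
    double best_split = 0.0;
    std::vector<std::pair<double, double>> xv(n);  // (x, y)
    for (int k = 0; k < mtry && k < p; ++k) {
      int v = vars[k];
      for (int i = 0; i < n; ++i)
        xv[i] = {X(idx[lo + i], v), y[idx[lo + i]]};
      std::sort(xv.begin(), xv.end());
      if (xv[0].first == xv[n - 1].first) continue;
      double sl = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        sl += xv[i].second;
        if (xv[i].first == xv[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        double sr = sum - sl;
        double gain = sl * sl / nl + sr * sr / nr - sum * sum / n;
        if (gain > best_gain) {
          best_gain = gain;
          best_var = v;
          best_split = 0.5 * (xv[i].first + xv[i + 1].first);
        }
      }
    }
    if (best_var < 0) return id;  // no usable split among candidates

    int mid = lo;  // partition idx by the chosen split
    for (int i = lo; i < hi; ++i)
      if (X(idx[i], best_var) <= best_split) std::swap(idx[i], idx[mid++]);
    if (mid == lo || mid == hi) return id;  // numeric ties; keep as leaf
    nodes[id].var = best_var;
    nodes[id].split = best_split;
    int l = build(lo, mid);
    nodes[id].left = l;
    int r = build(mid, hi);
    nodes[id].right = r;
    return id;
  }
};

double tree_predict(const NumericMatrix& tree, const double* x) {
  int node = 0;
  while ((int)tree(node, 0) >= 0) {
    int v = (int)tree(node, 0);
    node = (x[v] <= tree(node, 1)) ? (int)tree(node, 2) : (int)tree(node, 3);
  }
  return tree(node, 4);
}

NumericMatrix pack_tree(const std::vector<Node>& nodes) {
  NumericMatrix m(nodes.size(), 5);
  for (size_t i = 0; i < nodes.size(); ++i) {
    m(i, 0) = nodes[i].var;
    m(i, 1) = nodes[i].split;
    m(i, 2) = nodes[i].left;
    m(i, 3) = nodes[i].right;
    m(i, 4) = nodes[i].pred;
  }
  return m;
}

}  // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int ntree, int mtry,
                int sampsize, NumericVector samp_weights, int nodesize,
                int seed) {
  int n = X.nrow();
  std::mt19937 rng(seed);
  bool weighted = samp_weights.size() == (R_xlen_t)n;
  std::vector<double> w(n, 1.0);
  if (weighted) for (int i = 0; i < n; ++i) w[i] = samp_weights[i];
  std::discrete_distribution<int> draw(w.begin(), w.end());

  List trees(ntree);
  IntegerMatrix inbag(n, ntree);
  NumericVector oob_sum(n, 0.0);
  IntegerVector oob_cnt(n, 0);

  for (int t = 0; t < ntree; ++t) {
    TreeBuilder tb(X, y, mtry, nodesize, rng);
    tb.idx.resize(sampsize);
    for (int i = 0; i < sampsize; ++i) {
      int s = draw(rng);
      tb.idx[i] = s;
      inbag(s, t)++;
    }
    tb.build(0, sampsize);
    NumericMatrix tr = pack_tree(tb.nodes);
    trees[t] = tr;
    std::vector<double> row(X.ncol());
    for (int i = 0; i < n; ++i) {
      if (inbag(i, t) == 0) {
        for (int j = 0; j < X.ncol(); ++j) row[j] = X(i, j);
        oob_sum[i] += tree_predict(tr, row.data());
        oob_cnt[i]++;
      }
    }
  }
  NumericVector oob_pred(n);
  for (int i = 0; i < n; ++i)
    oob_pred[i] = oob_cnt[i] > 0 ? oob_sum[i] / oob_cnt[i] : NA_REAL;
  return List::create(_["trees"] = trees, _["inbag"] = inbag,
                      _["oob_pred"] = oob_pred, _["oob_count"] = oob_cnt);
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), ntree = trees.size();
  NumericVector out(n, 0.0);
  std::vector<double> row(X.ncol());
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < X.ncol(); ++j) row[j] = X(i, j);
    double s = 0.0;
    for (int t = 0; t < ntree; ++t)
      s += tree_predict(as<NumericMatrix>(trees[t]), row.data());
    out[i] = s / ntree;
  }
  return out;
}

// Permutation importance: mean increase in per-tree out-of-bag MSE when one
// variable's OOB values are shuffled (the randomForest %IncMSE numerator).
// [[Rcpp::export]]
NumericVector rf_importance_cpp(List trees, IntegerMatrix inbag,
                                NumericMatrix X, NumericVector y, int seed) {
  int n = X.nrow(), p = X.ncol(), ntree = trees.size();
  std::mt19937 rng(seed);
  std::vector<double> imp(p, 0.0);
  std::vector<int> ntree_used(p, 0);
  std::vector<int> oob;

  for (int t = 0; t < ntree; ++t) {
    NumericMatrix tr = trees[t];
    oob.clear();
    for (int i = 0; i < n; ++i)
      if (inbag(i, t) == 0) oob.push_back(i);
    int m = (int)oob.size();
    if (m < 2) continue;
    // cache the OOB rows once; per variable only one entry changes
    std::vector<std::vector<double>> rows(m, std::vector<double>(p));
    double base = 0.0;
    for (int i = 0; i < m; ++i) {
      for (int j = 0; j < p; ++j) rows[i][j] = X(oob[i], j);
      double e = tree_predict(tr, rows[i].data()) - y[oob[i]];
      base += e * e;
    }
    base /= m;
    std::vector<int> perm(oob);
    for (int v = 0; v < p; ++v) {
      std::shuffle(perm.begin(), perm.end(), rng);
      double err = 0.0;
      for (int i = 0; i < m; ++i) {
        double keep = rows[i][v];
        rows[i][v] = X(perm[i], v);
        double e = tree_predict(tr, rows[i].data()) - y[oob[i]];
        rows[i][v] = keep;
        err += e * e;
      }
      err /= m;
      imp[v] += err - base;
      ntree_used[v]++;
    }
  }
  NumericVector out(p);
  for (int v = 0; v < p; ++v)
    out[v] = ntree_used[v] > 0 ? imp[v] / ntree_used[v] : 0.0;
  return out;
}
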