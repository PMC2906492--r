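// CART trees for the random-forest learners. Sampling (bootstrap /
// down-sampling) happens on the R side so the class-balance contract is
// observable there; this file only grows single trees and runs predictions.
// Randomness (per-split feature subsampling) comes from R's RNG so that
// set.seed() governs the whole fit.

#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct TreeBuf {
  std::vector<int> var;       // split feature (0-based), -1 for leaf
  std::vector<double> split;  // threshold: x[var] <= split goes left
  std::vector<int> left, right;
  std::vector<double> pred;   // leaf value: class-1 fraction or mean
};

// sample m distinct ints from 0..p-1 using R's RNG (partial Fisher-Yates)
static void sampleFeatures(int p, int m, std::vector<int> &feat) {
  static std::vector<int> pool;
  pool.resize(p);
  for (int i = 0; i < p; ++i) pool[i] = i;
  feat.clear();
  for (int i = 0; i < m; ++i) {
    int j = i + (int)(unif_rand() * (p - i));
    if (j >= p) j = p - 1;
    std::swap(pool[i], pool[j]);
    feat.push_back(pool[i]);
  }
}

struct BestSplit {
  int var = -1;
  double split = 0.0, gain = 0.0;
};

// search the best threshold on one feature; returns improvement in the
// node impurity (Gini count for classification, SSE for regression)
static bool bestOnFeature(const NumericMatrix &X, const NumericVector &y,
                          const std::vector<int> &idx, int f, bool cls,
                          double parentImp, BestSplit &out) {
  const int n = (int)idx.size();
  static std::vector<std::pair<double, double>> vy;
  vy.clear();
  vy.reserve(n);
  for (int i = 0; i < n; ++i) vy.emplace_back(X(idx[i], f), y[idx[i]]);
  std::sort(vy.begin(), vy.end());
  if (vy.front().first == vy.back().first) return false;

  double sumAll = 0.0;
  for (auto &p : vy) sumAll += p.second;

  bool found = false;
  double sumL = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    sumL += vy[i].second;
    if (vy[i].first == vy[i + 1].first) continue;
    const int nL = i + 1, nR = n - nL;
    double childImp;
    if (cls) {
      const double pL = sumL / nL, pR = (sumAll - sumL) / nR;
      childImp = nL * 2.0 * pL * (1.0 - pL) + nR * 2.0 * pR * (1.0 - pR);
    } else {
      // SSE decomposition: impurity = sum y^2 - sum^2/n; sum y^2 cancels
      childImp = -(sumL * sumL / nL +
                   (sumAll - sumL) * (sumAll - sumL) / nR);
    }
    const double gain = parentImp - childImp;
    if (gain > out.gain + 1e-12) {
      out.gain = gain;
      out.var = f;
      out.split = vy[i].first + (vy[i + 1].first - vy[i].first) / 2.0;
      found = true;
    }
  }
  return found;
}

static double nodeImpurity(const NumericVector &y, const std::vector<int> &idx,
                           bool cls) {
  const int n = (int)idx.size();
  double s = 0.0;
  for (int i : idx) s += y[i];
  if (cls) {
    const double p = s / n;
    return n * 2.0 * p * (1.0 - p);
  }
  return -(s * s / n);
}

static int growNode(TreeBuf &T, const NumericMatrix &X, const NumericVector &y,
                    std::vector<int> &idx, int mtry, int minnode, bool cls) {
  const int n = (int)idx.size();
  double s = 0.0;
  for (int i : idx) s += y[i];
  const double mean = s / n;

  const int node = (int)T.var.size();
  T.var.push_back(-1);
  T.split.push_back(0.0);
  T.left.push_back(-1);
  T.right.push_back(-1);
  T.pred.push_back(mean);

  bool pure = cls ? (s == 0.0 || s == (double)n) : true;
  if (!cls) {
    for (int i : idx)
      if (y[i] != y[idx[0]]) { pure = false; break; }
  }
  if (n <= minnode || pure) return node;

  const double parentImp = nodeImpurity(y, idx, cls);
  BestSplit best;
  std::vector<int> feat;
  sampleFeatures(X.ncol(), mtry, feat);
  for (int f : feat) bestOnFeature(X, y, idx, f, cls, parentImp, best);
  if (best.var < 0) return node;

  std::vector<int> li, ri;
  li.reserve(n);
  ri.reserve(n);
  for (int i : idx)
    (X(i, best.var) <= best.split ? li : ri).push_back(i);
  if (li.empty() || ri.empty()) return node;

  idx.clear();
  idx.shrink_to_fit();
  T.var[node] = best.var;
  T.split[node] = best.split;
  const int l = growNode(T, X, y, li, mtry, minnode, cls);
  T.left[node] = l;
  const int r = growNode(T, X, y, ri, mtry, minnode, cls);
  T.right[node] = r;
  return node;
}

}  // namespace

// [[Rcpp::export]]
List cpp_build_tree(NumericMatrix X, NumericVector y, IntegerVector idx,
                    int mtry, int minnode, bool classification) {
  TreeBuf T;
  std::vector<int> rows(idx.begin(), idx.end());
  RNGScope scope;
  growNode(T, X, y, rows, mtry, minnode, classification);
  return List::create(_["var"] = wrap(T.var), _["split"] = wrap(T.split),
                      _["left"] = wrap(T.left), _["right"] = wrap(T.right),
                      _["pred"] = wrap(T.pred));
}

// [[Rcpp::export]]
NumericVector cpp_predict_tree(List tree, NumericMatrix X) {
  IntegerVector var = tree["var"], left = tree["left"], right = tree["right"];
  NumericVector split = tree["split"], pred = tree["pred"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (var[node] >= 0)
      node = (X(i, var[node]) <= split[node]) ? left[node] : right[node];
    out[i] = pred[node];
  }
  return out;
}
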