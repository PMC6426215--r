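#include <Rcpp.h>
using namespace Rcpp;

// CART regression forest: bootstrap resamples, variance-reduction splits
// over mtry randomly drawn features, unpruned down to min_node observations
// per leaf. Trees are stored as parallel arrays (feature = -1 marks a leaf).
// R's RNG drives bootstrap and feature sampling, so set.seed() fixes the
// forest exactly.

struct TreeBuf {
  std::vector<int> feature, left, right;
  std::vector<double> threshold, value;
};

static int build_node(const NumericMatrix& X, const NumericVector& y,
                      std::vector<int>& idx, int lo, int hi,
                      int mtry, int min_node, TreeBuf& T) {
  const int n = hi - lo;
  double sum = 0.0, ss = 0.0;
  for (int k = lo; k < hi; ++k) { sum += y[idx[k]]; ss += y[idx[k]] * y[idx[k]]; }
  const double node_mean = sum / n;
  const double node_sse = ss - sum * sum / n;
  const int me = T.feature.size();
  T.feature.push_back(-1); T.threshold.push_back(0.0);
  T.left.push_back(-1); T.right.push_back(-1); T.value.push_back(node_mean);
  if (n < 2 * min_node || n < 2 || node_sse <= 1e-12) return me;

  const int p = X.ncol();
  // sample mtry features without replacement (partial Fisher-Yates, R RNG)
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  const int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) {
    int r = j + (int)(R::unif_rand() * (p - j));
    if (r >= p) r = p - 1;
    std::swap(feats[j], feats[r]);
  }

  double best_gain = 0.0, best_thr = 0.0;
  int best_f = -1;
  std::vector<std::pair<double, int> > vals(n);
  for (int jj = 0; jj < m; ++jj) {
    const int f = feats[jj];
    for (int k = 0; k < n; ++k) {
      const int i = idx[lo + k];
      vals[k] = std::make_pair(X(i, f), i);
    }
    std::sort(vals.begin(), vals.end());
    double lsum = 0.0;
    for (int k = 0; k < n - 1; ++k) {
      lsum += y[vals[k].second];
      const int nl = k + 1, nr = n - nl;
      if (nl < min_node || nr < min_node) continue;
      if (vals[k + 1].first <= vals[k].first) continue;  // tie: no cut here
      const double rsum = sum - lsum;
      const double gain = lsum * lsum / nl + rsum * rsum / nr - sum * sum / n;
      if (gain > best_gain + 1e-12) {
        best_gain = gain; best_f = f;
        best_thr = 0.5 * (vals[k].first + vals[k + 1].first);
      }
    }
  }
  if (best_f < 0) return me;

  int mid = lo;
  for (int k = lo; k < hi; ++k)
    if (X(idx[k], best_f) <= best_thr) std::swap(idx[k], idx[mid++]);
  if (mid == lo || mid == hi) return me;
  T.feature[me] = best_f; T.threshold[me] = best_thr;
  const int l = build_node(X, y, idx, lo, mid, mtry, min_node, T);
  const int r = build_node(X, y, idx, mid, hi, mtry, min_node, T);
  T.left[me] = l; T.right[me] = r;
  return me;
}

static double predict_tree(const TreeBuf& T, const NumericMatrix& X, int i) {
  int node = 0;
  while (T.feature[node] >= 0)
    node = (X(i, T.feature[node]) <= T.threshold[node]) ? T.left[node]
                                                        : T.right[node];
  return T.value[node];
}

// [[Rcpp::export]]
List rf_fit(NumericMatrix X, NumericVector y, int ntree, int mtry,
            int min_node) {
  const int n = X.nrow();
  List trees(ntree);
  NumericVector oob_sum(n, 0.0);
  IntegerVector oob_n(n, 0);
  std::vector<int> idx(n), inbag(n);
  for (int t = 0; t < ntree; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int k = 0; k < n; ++k) {
      int r = (int)(R::unif_rand() * n);
      if (r >= n) r = n - 1;
      idx[k] = r;
      inbag[r] = 1;
    }
    TreeBuf T;
    build_node(X, y, idx, 0, n, mtry, min_node, T);
    for (int i = 0; i < n; ++i) {
      if (!inbag[i]) {
        oob_sum[i] += predict_tree(T, X, i);
        oob_n[i] += 1;
      }
    }
    trees[t] = List::create(
        _["feature"] = IntegerVector(T.feature.begin(), T.feature.end()),
        _["threshold"] = NumericVector(T.threshold.begin(), T.threshold.end()),
        _["left"] = IntegerVector(T.left.begin(), T.left.end()),
        _["right"] = IntegerVector(T.right.begin(), T.right.end()),
        _["value"] = NumericVector(T.value.begin(), T.value.end()));
  }
  NumericVector oob(n);
  for (int i = 0; i < n; ++i)
    oob[i] = oob_n[i] > 0 ? oob_sum[i] / oob_n[i] : NA_REAL;
  return List::create(_["trees"] = trees, _["oob"] = oob);
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), ntree = trees.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    TreeBuf T;
    IntegerVector f = tr["feature"], l = tr["left"], r = tr["right"];
    NumericVector thr = tr["threshold"], v = tr["value"];
    T.feature.assign(f.begin(), f.end());
    T.left.assign(l.begin(), l.end());
    T.right.assign(r.begin(), r.end());
    T.threshold.assign(thr.begin(), thr.end());
    T.value.assign(v.begin(), v.end());
    for (int i = 0; i < n; ++i) out[i] += predict_tree(T, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}
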