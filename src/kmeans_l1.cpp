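#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// One run of Lloyd-style k-means under Manhattan (L1) distance:
// points are assigned to the L1-nearest centroid (ties to the lowest index)
// and centroids are updated to the coordinate-wise median of their members,
// the L1-optimal location. An emptied cluster is re-seeded with the point
// farthest (L1) from its current centroid.

static double col_median(std::vector<double>& v) {
  const size_t n = v.size();
  std::sort(v.begin(), v.end());
  if (n % 2 == 1) return v[n / 2];
  return 0.5 * (v[n / 2 - 1] + v[n / 2]);
}

// [[Rcpp::export(name = ".kmeans_l1_run")]]
List kmeans_l1_run(NumericMatrix X, NumericMatrix init, int max_iter = 100) {
  const int M = X.nrow(), D = X.ncol(), k = init.nrow();
  NumericMatrix C(clone(init));
  IntegerVector labels(M, -1);
  NumericVector d_own(M);
  std::vector<double> obj_trace;
  bool changed = true;
  int it = 0;

  while (changed && it < max_iter) {
    ++it;
    changed = false;
    double obj = 0.0;
    // assignment
    for (int i = 0; i < M; ++i) {
      double best = R_PosInf; int bj = 0;
      for (int j = 0; j < k; ++j) {
        double d = 0.0;
        for (int c = 0; c < D; ++c) d += std::fabs(X(i, c) - C(j, c));
        if (d < best - 1e-15) { best = d; bj = j; }
      }
      if (labels[i] != bj) { labels[i] = bj; changed = true; }
      d_own[i] = best;
      obj += best;
    }
    bool any_empty = false;
    for (int j = 0; j < k && !any_empty; ++j) {
      int cnt = 0;
      for (int i = 0; i < M; ++i) if (labels[i] == j) ++cnt;
      if (cnt == 0) any_empty = true;
    }
    // stop on label stability or an objective plateau (relative 1e-7)
    if (!any_empty && !obj_trace.empty() &&
        obj_trace.back() - obj < 1e-7 * std::max(1.0, obj_trace.back())) {
      obj_trace.push_back(obj);
      break;
    }
    obj_trace.push_back(obj);
    if (!changed && !any_empty && it > 1) break;
    // empty-cluster repair: farthest point becomes a singleton centroid
    for (int j = 0; j < k; ++j) {
      int cnt = 0;
      for (int i = 0; i < M; ++i) if (labels[i] == j) ++cnt;
      if (cnt == 0) {
        int far = 0; double fd = -1.0;
        for (int i = 0; i < M; ++i)
          if (d_own[i] > fd) { fd = d_own[i]; far = i; }
        labels[far] = j;
        d_own[far] = 0.0;
        changed = true;
      }
    }
    // median update
    std::vector<double> vals;
    for (int j = 0; j < k; ++j) {
      for (int c = 0; c < D; ++c) {
        vals.clear();
        for (int i = 0; i < M; ++i)
          if (labels[i] == j) vals.push_back(X(i, c));
        if (!vals.empty()) C(j, c) = col_median(vals);
      }
    }
  }

  // final objective under final centroids/labels
  double obj = 0.0;
  for (int i = 0; i < M; ++i) {
    double d = 0.0;
    for (int c = 0; c < D; ++c) d += std::fabs(X(i, c) - C(labels[i], c));
    obj += d;
  }
  obj_trace.push_back(obj);

  return List::create(_["labels"] = labels, _["centroids"] = C,
                      _["objective"] = obj,
                      _["objective_trace"] = wrap(obj_trace),
                      _["iterations"] = it);
}

// Total L1 distance from each row of X to each row of C (for validity index).
// [[Rcpp::export(name = ".l1_dist_to_centroids")]]
NumericMatrix l1_dist_to_centroids(NumericMatrix X, NumericMatrix C) {
  const int M = X.nrow(), D = X.ncol(), k = C.nrow();
  NumericMatrix out(M, k);
  for (int i = 0; i < M; ++i)
    for (int j = 0; j < k; ++j) {
      double d = 0.0;
      for (int c = 0; c < D; ++c) d += std::fabs(X(i, c) - C(j, c));
      out(i, j) = d;
    }
  return out;
}
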