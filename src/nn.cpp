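#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Brute-force nearest-neighbor queries for small/medium clouds (<= ~5e4
// points). Registration and evaluation only ever need exact NN on clouds of
// this size, so no spatial index is built.

// [[Rcpp::export]]
List cpp_nn(NumericMatrix query, NumericMatrix ref) {
  const int n = query.nrow(), m = ref.nrow();
  IntegerVector idx(n);
  NumericVector dist(n);
  const double *qx = &query(0, 0), *qy = &query(0, 1), *qz = &query(0, 2);
  const double *rx = &ref(0, 0), *ry = &ref(0, 1), *rz = &ref(0, 2);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bi = -1;
    const double x = qx[i], y = qy[i], z = qz[i];
    for (int j = 0; j < m; ++j) {
      const double dx = x - rx[j], dy = y - ry[j], dz = z - rz[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bi = j; }
    }
    idx[i] = bi + 1;  // 1-based
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}

// Per-point squared distances to all others, with the k smallest selected by
// nth_element; returns an n x k matrix of the k nearest-neighbor distances
// (sorted ascending), excluding the point itself.
// [[Rcpp::export]]
NumericMatrix cpp_knn_dists(NumericMatrix pts, int k) {
  const int n = pts.nrow();
  if (k >= n) stop("k must be smaller than the number of points");
  NumericMatrix out(n, k);
  const double *px = &pts(0, 0), *py = &pts(0, 1), *pz = &pts(0, 2);
  std::vector<double> d2(n);
  for (int i = 0; i < n; ++i) {
    const double x = px[i], y = py[i], z = pz[i];
    for (int j = 0; j < n; ++j) {
      const double dx = x - px[j], dy = y - py[j], dz = z - pz[j];
      d2[j] = dx * dx + dy * dy + dz * dz;
    }
    d2[i] = R_PosInf;  // exclude self
    std::vector<double> tmp(d2);
    std::nth_element(tmp.begin(), tmp.begin() + (k - 1), tmp.end());
    std::sort(tmp.begin(), tmp.begin() + k);
    for (int c = 0; c < k; ++c) out(i, c) = std::sqrt(tmp[c]);
    d2[i] = 0.0;
  }
  return out;
}
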