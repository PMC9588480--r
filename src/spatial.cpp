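// Pairwise-distance kernels shared by the K estimators, the kernel intensity
// field and the k-nearest-neighbour summaries.  Contracts are exact Euclidean
// distances; ties D == r count as <= r.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// For each radius in `radii` (increasing, um), the number of unordered pairs
// with distance <= radius.
// [[Rcpp::export]]
NumericVector cpp_pair_count(NumericVector x, NumericVector y, NumericVector z,
                             NumericVector radii) {
  const int n = x.size(), m = radii.size();
  std::vector<double> r2(m);
  for (int k = 0; k < m; ++k) r2[k] = radii[k]*radii[k];
  std::vector<double> cnt(m, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i+1; j < n; ++j) {
      const double dx = x[i]-x[j], dy = y[i]-y[j], dz = z[i]-z[j];
      const double d2 = dx*dx + dy*dy + dz*dz;
      // first radius with r^2 >= d2
      int k = std::lower_bound(r2.begin(), r2.end(), d2) - r2.begin();
      if (k < m) cnt[k] += 1.0;
    }
  }
  for (int k = 1; k < m; ++k) cnt[k] += cnt[k-1];
  return NumericVector(cnt.begin(), cnt.end());
}

// For each radius, sum over ordered pairs i != j with D(i,j) <= r of
// 1/(lambda_i * lambda_j); `w` holds 1/lambda_i.
// [[Rcpp::export]]
NumericVector cpp_pair_weight_sum(NumericVector x, NumericVector y,
                                  NumericVector z, NumericVector w,
                                  NumericVector radii) {
  const int n = x.size(), m = radii.size();
  std::vector<double> r2(m);
  for (int k = 0; k < m; ++k) r2[k] = radii[k]*radii[k];
  std::vector<double> acc(m, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i+1; j < n; ++j) {
      const double dx = x[i]-x[j], dy = y[i]-y[j], dz = z[i]-z[j];
      const double d2 = dx*dx + dy*dy + dz*dz;
      int k = std::lower_bound(r2.begin(), r2.end(), d2) - r2.begin();
      if (k < m) acc[k] += 2.0 * w[i] * w[j];
    }
  }
  for (int k = 1; k < m; ++k) acc[k] += acc[k-1];
  return NumericVector(acc.begin(), acc.end());
}

// Sum_j exp(-|q - c_j|^2 / (2 h^2)) for each query point q.
// [[Rcpp::export]]
NumericVector cpp_gauss_sum(NumericMatrix q, NumericMatrix centers, double h) {
  const int nq = q.nrow(), nc = centers.nrow();
  const double inv2h2 = 1.0 / (2.0 * h * h);
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    double s = 0.0;
    const double qx = q(i,0), qy = q(i,1), qz = q(i,2);
    for (int j = 0; j < nc; ++j) {
      const double dx = qx - centers(j,0), dy = qy - centers(j,1),
                   dz = qz - centers(j,2);
      s += std::exp(-(dx*dx + dy*dy + dz*dz) * inv2h2);
    }
    out[i] = s;
  }
  return out;
}

// Weighted variant: Sum_j w_j exp(-|q - c_j|^2 / (2 h^2)); with
// drop_self = true, a centre within 1e-6 um of the query is skipped once
// (leave-one-out evaluation at the kernel's own source points).
// [[Rcpp::export]]
NumericVector cpp_gauss_wsum(NumericMatrix q, NumericMatrix centers,
                             NumericVector w, double h, bool drop_self) {
  const int nq = q.nrow(), nc = centers.nrow();
  const double inv2h2 = 1.0 / (2.0 * h * h);
  const double eps2 = 1e-12;
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    double s = 0.0;
    bool dropped = false;
    const double qx = q(i,0), qy = q(i,1), qz = q(i,2);
    for (int j = 0; j < nc; ++j) {
      const double dx = qx - centers(j,0), dy = qy - centers(j,1),
                   dz = qz - centers(j,2);
      const double d2 = dx*dx + dy*dy + dz*dz;
      if (drop_self && !dropped && d2 < eps2) { dropped = true; continue; }
      s += w[j] * std::exp(-d2 * inv2h2);
    }
    out[i] = s;
  }
  return out;
}
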