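#include <Rcpp.h>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Spectra are passed channels-in-rows (C x N) so that each point is a
// contiguous column of the column-major R matrix.

// Exact neighbourhood counts: number of points (self included) within
// `radius` of each point. metric: 1 = L1, 2 = L2. Accumulation is checked
// in blocks of 64 channels so far pairs abandon early.
// [[Rcpp::export(name = ".count_within_radius")]]
IntegerVector count_within_radius(NumericMatrix x, double radius, int metric) {
  const int C = x.nrow(), N = x.ncol();
  if (radius <= 0) stop("radius must be > 0");
  IntegerVector cnt(N);
  for (int i = 0; i < N; ++i) cnt[i] = 1;  // self-inclusion convention
  const double lim = (metric == 2) ? radius * radius : radius;
  for (int i = 0; i < N; ++i) {
    const double* xi = &x(0, i);
    for (int j = i + 1; j < N; ++j) {
      const double* xj = &x(0, j);
      double acc = 0.0;
      bool within = true;
      int c = 0;
      while (c < C) {
        const int stop_ = std::min(c + 64, C);
        if (metric == 2) {
          for (; c < stop_; ++c) {
            const double d = xi[c] - xj[c];
            acc += d * d;
          }
        } else {
          for (; c < stop_; ++c) acc += std::fabs(xi[c] - xj[c]);
        }
        if (acc > lim) { within = false; break; }
      }
      if (within) { ++cnt[i]; ++cnt[j]; }
    }
  }
  return cnt;
}

// Nearest centroid per point, ties broken by lowest centroid index.
// x: C x N points, cen: C x K centroids. Returns 1-based indices.
// [[Rcpp::export(name = ".nearest_centroid_idx")]]
IntegerVector nearest_centroid_idx(NumericMatrix x, NumericMatrix cen,
                                   int metric) {
  const int C = x.nrow(), N = x.ncol(), K = cen.ncol();
  if (cen.nrow() != C) stop("centroid/point channel mismatch");
  IntegerVector out(N);
  for (int i = 0; i < N; ++i) {
    const double* xi = &x(0, i);
    double best = R_PosInf;
    int best_k = 0;
    for (int k = 0; k < K; ++k) {
      const double* ck = &cen(0, k);
      double acc = 0.0;
      bool beaten = false;
      int c = 0;
      while (c < C) {
        const int stop_ = std::min(c + 64, C);
        if (metric == 2) {
          for (; c < stop_; ++c) {
            const double d = xi[c] - ck[c];
            acc += d * d;
          }
        } else {
          for (; c < stop_; ++c) acc += std::fabs(xi[c] - ck[c]);
        }
        if (acc >= best) { beaten = true; break; }  // strict < keeps lowest id
      }
      if (!beaten && acc < best) { best = acc; best_k = k; }
    }
    out[i] = best_k + 1;
  }
  return out;
}

// Pentadiagonal LDL^T solve of (diag(w) + lambda * D2' D2) z = w * y,
// the normal equations of Whittaker smoothing with a second-difference
// penalty. Used by the asymmetric least squares baseline.
static void penta_solve(const std::vector<double>& w, double lambda,
                        const double* y, int n, std::vector<double>& z,
                        std::vector<double>& D, std::vector<double>& l1,
                        std::vector<double>& l2) {
  // band coefficients of lambda * D2'D2
  // diag: lambda * (1, 5, 6, ..., 6, 5, 1)
  // off1: lambda * (-2, -4, ..., -4, -2)
  // off2: lambda * 1
  for (int i = 0; i < n; ++i) {
    double a0;
    if (i == 0 || i == n - 1) a0 = 1.0;
    else if (i == 1 || i == n - 2) a0 = 5.0;
    else a0 = 6.0;
    a0 = w[i] + lambda * a0;
    const double a1 = (i < n - 1)
      ? lambda * ((i == 0 || i == n - 2) ? -2.0 : -4.0) : 0.0;
    const double a2 = (i < n - 2) ? lambda : 0.0;
    const double m1 = (i >= 1) ? l1[i - 1] : 0.0;
    const double m2 = (i >= 2) ? l2[i - 2] : 0.0;
    double d = a0;
    if (i >= 1) d -= m1 * m1 * D[i - 1];
    if (i >= 2) d -= m2 * m2 * D[i - 2];
    D[i] = d;
    if (i < n - 1) {
      double v = a1;
      if (i >= 1) v -= l2[i - 1] * l1[i - 1] * D[i - 1];
      l1[i] = v / d;
    }
    if (i < n - 2) l2[i] = a2 / d;
  }
  // forward solve L u = w*y
  for (int i = 0; i < n; ++i) {
    double v = w[i] * y[i];
    if (i >= 1) v -= l1[i - 1] * z[i - 1];
    if (i >= 2) v -= l2[i - 2] * z[i - 2];
    z[i] = v;
  }
  for (int i = 0; i < n; ++i) z[i] /= D[i];
  // back solve L^T x = u
  for (int i = n - 1; i >= 0; --i) {
    double v = z[i];
    if (i + 1 < n) v -= l1[i] * z[i + 1];
    if (i + 2 < n) v -= l2[i] * z[i + 2];
    z[i] = v;
  }
}

// Asymmetric least squares baseline (Eilers), one spectrum per column.
// Returns the fitted baseline for each column.
// [[Rcpp::export(name = ".asls_baseline_mat")]]
NumericMatrix asls_baseline_mat(NumericMatrix y, double lambda, double p,
                                int niter) {
  const int n = y.nrow(), m = y.ncol();
  if (n < 3) stop("need at least 3 channels");
  NumericMatrix out(n, m);
  std::vector<double> w(n), z(n), D(n), l1(n), l2(n);
  for (int j = 0; j < m; ++j) {
    const double* yj = &y(0, j);
    std::fill(w.begin(), w.end(), 1.0);
    for (int it = 0; it < niter; ++it) {
      penta_solve(w, lambda, yj, n, z, D, l1, l2);
      for (int i = 0; i < n; ++i) w[i] = (yj[i] > z[i]) ? p : 1.0 - p;
    }
    for (int i = 0; i < n; ++i) out(i, j) = z[i];
  }
  return out;
}
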