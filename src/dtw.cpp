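#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Banded dynamic-time-warping alignment cost between two sequences.
// Point cost is the squared difference; the returned distance is the square
// root of the minimal cumulative cost over monotone warping paths with
// |i - j| <= band (Sakoe-Chiba). band < 0 means unconstrained.
static double dtw_core(const double* x, int n, const double* y, int m,
                       long band) {
  const double INF = std::numeric_limits<double>::infinity();
  if (band < 0) band = (n > m ? n : m);
  // path feasibility for unequal lengths requires band >= |n - m|
  long diff = n > m ? n - m : m - n;
  if (band < diff) return NA_REAL;
  std::vector<double> prev(m + 1, INF), cur(m + 1, INF);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    long lo = i - band; if (lo < 1) lo = 1;
    long hi = i + band; if (hi > m) hi = m;
    for (long j = lo; j <= hi; ++j) {
      double d = x[i - 1] - y[j - 1];
      double best = prev[j - 1];            // diagonal
      if (prev[j] < best) best = prev[j];   // insertion
      if (cur[j - 1] < best) best = cur[j - 1]; // deletion
      cur[j] = d * d + best;
    }
    std::swap(prev, cur);
  }
  return std::sqrt(prev[m]);
}

// [[Rcpp::export]]
double dtw_dist_cpp(NumericVector x, NumericVector y, double band) {
  long b = R_finite(band) ? (long)band : -1;
  double d = dtw_core(x.begin(), x.size(), y.begin(), y.size(), b);
  if (ISNA(d)) stop("band radius too narrow for the length difference");
  return d;
}

// Pairwise DTW distances between the rows of X (equal-length series).
// [[Rcpp::export]]
NumericMatrix dtw_pairwise_cpp(NumericMatrix X, double band) {
  int n = X.nrow(), m = X.ncol();
  long b = R_finite(band) ? (long)band : -1;
  NumericMatrix D(n, n);
  std::vector<std::vector<double>> rows(n, std::vector<double>(m));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) rows[i][j] = X(i, j);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = dtw_core(rows[i].data(), m, rows[j].data(), m, b);
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}

// Cross DTW distances between rows of Q (queries) and rows of X (train).
// [[Rcpp::export]]
NumericMatrix dtw_cross_cpp(NumericMatrix Q, NumericMatrix X, double band) {
  if (Q.ncol() != X.ncol()) stop("series lengths differ");
  int nq = Q.nrow(), nx = X.nrow(), m = X.ncol();
  long b = R_finite(band) ? (long)band : -1;
  NumericMatrix D(nq, nx);
  std::vector<double> q(m), x(m);
  for (int i = 0; i < nq; ++i) {
    for (int k = 0; k < m; ++k) q[k] = Q(i, k);
    for (int j = 0; j < nx; ++j) {
      for (int k = 0; k < m; ++k) x[k] = X(j, k);
      D(i, j) = dtw_core(q.data(), m, x.data(), m, b);
    }
  }
  return D;
}
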