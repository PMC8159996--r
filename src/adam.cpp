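#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// In-place Adam update. p, m and v are modified directly: between
// optimizer steps the trainer is their sole owner, so skipping R's
// copy-on-write removes the dominant allocation cost of training.
// [[Rcpp::export]]
void adam_update_inplace(NumericVector p, NumericVector m, NumericVector v,
                         NumericVector g, double lr, double b1, double b2,
                         double eps, double corr1, double corr2) {
  R_xlen_t n = p.size();
  if (m.size() != n || v.size() != n || g.size() != n)
    stop("adam_update_inplace: length mismatch");
  double *pp = REAL(p), *pm = REAL(m), *pv = REAL(v), *pg = REAL(g);
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = pg[i];
    pm[i] = b1 * pm[i] + (1.0 - b1) * gi;
    pv[i] = b2 * pv[i] + (1.0 - b2) * gi * gi;
    pp[i] -= lr * (pm[i] / corr1) / (std::sqrt(pv[i] / corr2) + eps);
  }
}

// Incremental mean used for tail (Polyak) averaging of weights:
// avg += (x - avg) / count, in place.
// [[Rcpp::export]]
void incr_mean_inplace(NumericVector avg, NumericVector x, double count) {
  R_xlen_t n = avg.size();
  if (x.size() != n) stop("incr_mean_inplace: length mismatch");
  double *pa = REAL(avg), *px = REAL(x);
  for (R_xlen_t i = 0; i < n; ++i)
    pa[i] += (px[i] - pa[i]) / count;
}

// Fused pad + im2col gather: idx holds 1-based rows into x, or 0 for
// positions that fall in the zero padding.
// [[Rcpp::export]]
NumericMatrix gather_cols(NumericMatrix x, IntegerVector idx) {
  R_xlen_t N = x.ncol(), M = idx.size();
  NumericMatrix out((int) M, (int) N);
  const int *pi = INTEGER(idx);
  for (R_xlen_t c = 0; c < N; ++c) {
    const double *xc = &x(0, (int) c);
    double *oc = &out(0, (int) c);
    for (R_xlen_t r = 0; r < M; ++r) {
      int id = pi[r];
      oc[r] = id ? xc[id - 1] : 0.0;
    }
  }
  return out;
}

// Transposed counterpart: accumulate column gradients back into the
// (unpadded) input; padding positions (idx 0) are dropped.
// [[Rcpp::export]]
NumericMatrix scatter_add(NumericMatrix d, IntegerVector idx, int nrow_out) {
  R_xlen_t N = d.ncol(), M = idx.size();
  NumericMatrix out(nrow_out, (int) N);
  const int *pi = INTEGER(idx);
  for (R_xlen_t c = 0; c < N; ++c) {
    const double *dc = &d(0, (int) c);
    double *oc = &out(0, (int) c);
    for (R_xlen_t r = 0; r < M; ++r) {
      int id = pi[r];
      if (id) oc[id - 1] += dc[r];
    }
  }
  return out;
}
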