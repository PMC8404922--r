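#include <Rcpp.h>
using namespace Rcpp;

// Row-gather for im2col: x is (F, N), idx is 1-based rows into x with 0
// meaning an implicit zero row (padding). Returns (length(idx), N).
// [[Rcpp::export(rng = false)]]
NumericMatrix gather_rows(const NumericMatrix& x, const IntegerVector& idx) {
  const int m = idx.size(), n = x.ncol(), f = x.nrow();
  NumericMatrix out(m, n);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int j = 0; j < n; ++j) {
    const double* xc = xp + (size_t)j * f;
    double* oc = op + (size_t)j * m;
    for (int i = 0; i < m; ++i) {
      const int r = idx[i];
      oc[i] = (r > 0) ? xc[r - 1] : 0.0;
    }
  }
  return out;
}

// Adjoint of gather_rows: accumulates rows of d (length(idx), N) into an
// (nrow, N) result at positions idx; idx == 0 rows are dropped.
// [[Rcpp::export(rng = false)]]
NumericMatrix scatter_rows(const NumericMatrix& d, const IntegerVector& idx,
                           const int nrow) {
  const int m = idx.size(), n = d.ncol();
  NumericMatrix out(nrow, n);
  const double* dp = d.begin();
  double* op = out.begin();
  for (int j = 0; j < n; ++j) {
    const double* dc = dp + (size_t)j * m;
    double* oc = op + (size_t)j * nrow;
    for (int i = 0; i < m; ++i) {
      const int r = idx[i];
      if (r > 0) oc[r - 1] += dc[i];
    }
  }
  return out;
}
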