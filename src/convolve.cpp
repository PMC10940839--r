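#include <Rcpp.h>
using namespace Rcpp;

// Reflected (half-sample symmetric) index into [0, n)
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable 2D cross-correlation with reflected borders.
// kr runs along the row index (dim 1), kc along the column index (dim 2).
// Both kernels must have odd length; the centre tap is at (length-1)/2.
// Matrices are column-major, so both passes accumulate over contiguous
// columns.
// [[Rcpp::export(name = ".sepconv2_cpp")]]
NumericMatrix sepconv2_cpp(const NumericMatrix& img,
                           const NumericVector& kr,
                           const NumericVector& kc) {
  const int nr = img.nrow(), nc = img.ncol();
  const int mr = kr.size(), mc = kc.size();
  const int hr = (mr - 1) / 2, hc = (mc - 1) / 2;

  NumericMatrix tmp(nr, nc), out(nr, nc);

  // pass 1: along rows (dim 1), within each (contiguous) column
  for (int c = 0; c < nc; ++c) {
    const double* col = &img(0, c);
    double* tcol = &tmp(0, c);
    const int lo = (hr < nr) ? hr : nr;
    const int hi = (nr - hr > lo) ? nr - hr : lo;
    for (int r = 0; r < lo; ++r) {
      double acc = 0.0;
      for (int k = 0; k < mr; ++k)
        acc += col[reflect_idx(r - hr + k, nr)] * kr[k];
      tcol[r] = acc;
    }
    for (int r = lo; r < hi; ++r) {
      double acc = 0.0;
      const double* p = col + r - hr;
      for (int k = 0; k < mr; ++k) acc += p[k] * kr[k];
      tcol[r] = acc;
    }
    for (int r = hi; r < nr; ++r) {
      double acc = 0.0;
      for (int k = 0; k < mr; ++k)
        acc += col[reflect_idx(r - hr + k, nr)] * kr[k];
      tcol[r] = acc;
    }
  }

  // pass 2: along columns (dim 2), accumulating whole columns at a time
  for (int c = 0; c < nc; ++c) {
    double* ocol = &out(0, c);
    for (int k = 0; k < mc; ++k) {
      const double w = kc[k];
      if (w == 0.0) continue;
      const double* scol = &tmp(0, reflect_idx(c - hc + k, nc));
      for (int r = 0; r < nr; ++r) ocol[r] += scol[r] * w;
    }
  }
  return out;
}
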