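// Hot inner kernels of the encoder layers. Everything else stays in R; these
// routines only remove allocation/indexing overhead around the BLAS calls.
#include <Rcpp.h>
using namespace Rcpp;

// y = x * a[col] + b[col]
// [[Rcpp::export]]
NumericMatrix cpp_col_affine(const NumericMatrix& x, const NumericVector& a,
                             const NumericVector& b) {
  const int n = x.nrow(), c = x.ncol();
  NumericMatrix y(n, c);
  for (int j = 0; j < c; ++j) {
    const double aj = a[j], bj = b[j];
    const double* xj = &x(0, j);
    double* yj = &y(0, j);
    for (int i = 0; i < n; ++i) yj[i] = xj[i] * aj + bj;
  }
  return y;
}

// y = (x - mu[col]) * s[col]   (batchnorm normalize)
// [[Rcpp::export]]
NumericMatrix cpp_col_center_scale(const NumericMatrix& x,
                                   const NumericVector& mu,
                                   const NumericVector& s) {
  const int n = x.nrow(), c = x.ncol();
  NumericMatrix y(n, c);
  for (int j = 0; j < c; ++j) {
    const double mj = mu[j], sj = s[j];
    const double* xj = &x(0, j);
    double* yj = &y(0, j);
    for (int i = 0; i < n; ++i) yj[i] = (xj[i] - mj) * sj;
  }
  return y;
}

// dx of train-mode batchnorm: (dxhat - m1[col] - xhat * m2[col]) * s[col]
// [[Rcpp::export]]
NumericMatrix cpp_bn_backward(const NumericMatrix& dxhat,
                              const NumericMatrix& xhat,
                              const NumericVector& m1,
                              const NumericVector& m2,
                              const NumericVector& s) {
  const int n = dxhat.nrow(), c = dxhat.ncol();
  NumericMatrix y(n, c);
  for (int j = 0; j < c; ++j) {
    const double m1j = m1[j], m2j = m2[j], sj = s[j];
    const double* dj = &dxhat(0, j);
    const double* xj = &xhat(0, j);
    double* yj = &y(0, j);
    for (int i = 0; i < n; ++i) yj[i] = (dj[i] - m1j - xj[i] * m2j) * sj;
  }
  return y;
}

// im2col for 1D same-padded convolution over n windows of t steps:
// input x is (n*t) x c (time fastest within window); output (n*t) x (k*c)
// with column block j holding x shifted by offset j - (k-1)/2, zero padded.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& x, int n, int t, int k) {
  const int c = x.ncol();
  const int rows = n * t;
  const int p = (k - 1) / 2;
  NumericMatrix out(rows, k * c);
  for (int j = 0; j < k; ++j) {
    const int off = j - p;
    for (int ch = 0; ch < c; ++ch) {
      const double* xc = &x(0, ch);
      double* oc = &out(0, j * c + ch);
      for (int w = 0; w < n; ++w) {
        const int base = w * t;
        int lo = std::max(0, -off), hi = std::min(t, t - off);
        for (int s = lo; s < hi; ++s) oc[base + s] = xc[base + s + off];
      }
    }
  }
  return out;
}

// adjoint of cpp_im2col: scatter-add dxcol back onto the input grid
// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& dxcol, int n, int t, int k,
                         int c) {
  const int rows = n * t;
  const int p = (k - 1) / 2;
  NumericMatrix out(rows, c);
  for (int j = 0; j < k; ++j) {
    const int off = j - p;
    for (int ch = 0; ch < c; ++ch) {
      const double* dc = &dxcol(0, j * c + ch);
      double* oc = &out(0, ch);
      for (int w = 0; w < n; ++w) {
        const int base = w * t;
        int lo = std::max(0, -off), hi = std::min(t, t - off);
        for (int s = lo; s < hi; ++s) oc[base + s + off] += dc[base + s];
      }
    }
  }
  return out;
}

// relu forward returning value; mask recomputed cheaply in backward
// [[Rcpp::export]]
NumericMatrix cpp_relu(const NumericMatrix& x) {
  const int len = x.size();
  NumericMatrix y(x.nrow(), x.ncol());
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int i = 0; i < len; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0;
  return y;
}

// dout masked by (x > 0)
// [[Rcpp::export]]
NumericMatrix cpp_relu_backward(const NumericMatrix& dout,
                                const NumericMatrix& x) {
  const int len = x.size();
  NumericMatrix y(dout.nrow(), dout.ncol());
  const double* dp = dout.begin();
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int i = 0; i < len; ++i) yp[i] = xp[i] > 0 ? dp[i] : 0;
  return y;
}
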