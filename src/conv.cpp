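#include <Rcpp.h>
using namespace Rcpp;

// Depthwise (grouped) 1-D convolution kernels and an IIR filter loop.
// Layout convention: activations are matrices of (T * n) rows and M feature
// columns, time fastest within each of the n stacked segments.  "same"
// padding follows the TF convention: pad_left = (k-1)/2, the extra sample
// (even k) goes on the right.

// [[Rcpp::export]]
NumericMatrix cpp_dwconv1d_same_fw(const NumericMatrix& X, const NumericMatrix& K, int T) {
  const int rows = X.nrow(), M = X.ncol(), k = K.nrow();
  const int n = rows / T, padL = (k - 1) / 2;
  NumericMatrix Y(rows, M);
  for (int m = 0; m < M; ++m) {
    for (int i = 0; i < n; ++i) {
      const int off = i * T;
      for (int t = 0; t < T; ++t) {
        double acc = 0.0;
        const int j0 = std::max(0, padL - t);
        const int j1 = std::min(k, T - t + padL);
        for (int j = j0; j < j1; ++j)
          acc += X(off + t + j - padL, m) * K(j, m);
        Y(off + t, m) = acc;
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_dwconv1d_same_bw(const NumericMatrix& X, const NumericMatrix& K,
                          const NumericMatrix& dY, int T) {
  const int rows = X.nrow(), M = X.ncol(), k = K.nrow();
  const int n = rows / T, padL = (k - 1) / 2;
  NumericMatrix dX(rows, M), dK(k, M);
  for (int m = 0; m < M; ++m) {
    for (int i = 0; i < n; ++i) {
      const int off = i * T;
      for (int t = 0; t < T; ++t) {
        const double g = dY(off + t, m);
        if (g == 0.0) continue;
        const int j0 = std::max(0, padL - t);
        const int j1 = std::min(k, T - t + padL);
        for (int j = j0; j < j1; ++j) {
          dX(off + t + j - padL, m) += g * K(j, m);
          dK(j, m) += g * X(off + t + j - padL, m);
        }
      }
    }
  }
  return List::create(_["dX"] = dX, _["dK"] = dK);
}

// Depthwise spatial convolution collapsing the channel axis.
// A: array (T, C*n, F1) — slice f holds, for sample i and channel c,
// column (i*C + c).  Wd: (C, F1*D) with column m = f*D + d.
// Output: matrix ((T*n), F1*D), time fastest per sample.

// [[Rcpp::export]]
NumericMatrix cpp_dwspatial_fw(const NumericVector& A, const NumericMatrix& Wd,
                               int C, int D) {
  IntegerVector dim = A.attr("dim");
  const int T = dim[0], S = dim[1], F1 = dim[2];
  const int n = S / C, M = F1 * D;
  NumericMatrix Y(T * n, M);
  const double* a = A.begin();
  for (int f = 0; f < F1; ++f) {
    const double* slab = a + (R_xlen_t)f * T * S;
    for (int d = 0; d < D; ++d) {
      const int m = f * D + d;
      for (int i = 0; i < n; ++i) {
        double* y = &Y(i * T, m);
        for (int c = 0; c < C; ++c) {
          const double w = Wd(c, m);
          const double* x = slab + (R_xlen_t)(i * C + c) * T;
          for (int t = 0; t < T; ++t) y[t] += w * x[t];
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_dwspatial_bw(const NumericVector& A, const NumericMatrix& Wd,
                      const NumericMatrix& dY, int C, int D) {
  IntegerVector dim = A.attr("dim");
  const int T = dim[0], S = dim[1], F1 = dim[2];
  const int n = S / C, M = F1 * D;
  NumericVector dA(A.size());
  dA.attr("dim") = dim;
  NumericMatrix dWd(C, M);
  const double* a = A.begin();
  double* da = dA.begin();
  for (int f = 0; f < F1; ++f) {
    const R_xlen_t slab = (R_xlen_t)f * T * S;
    for (int d = 0; d < D; ++d) {
      const int m = f * D + d;
      for (int i = 0; i < n; ++i) {
        const double* g = &dY(i * T, m);
        for (int c = 0; c < C; ++c) {
          const R_xlen_t col = slab + (R_xlen_t)(i * C + c) * T;
          const double w = Wd(c, m);
          double accw = 0.0;
          for (int t = 0; t < T; ++t) {
            da[col + t] += w * g[t];
            accw += a[col + t] * g[t];
          }
          dWd(c, m) += accw;
        }
      }
    }
  }
  return List::create(_["dA"] = dA, _["dWd"] = dWd);
}

// Direct-form II transposed IIR filter with initial conditions.

// [[Rcpp::export]]
NumericVector cpp_lfilter(const NumericVector& b, const NumericVector& a,
                          const NumericVector& x, const NumericVector& zi) {
  const int nb = b.size(), nx = x.size();
  const int nz = nb - 1;
  std::vector<double> z(nz, 0.0);
  for (int i = 0; i < nz && i < zi.size(); ++i) z[i] = zi[i];
  NumericVector y(nx);
  for (int t = 0; t < nx; ++t) {
    const double xt = x[t];
    const double yt = b[0] * xt + (nz > 0 ? z[0] : 0.0);
    for (int i = 0; i < nz - 1; ++i)
      z[i] = b[i + 1] * xt + z[i + 1] - a[i + 1] * yt;
    if (nz > 0) z[nz - 1] = b[nz] * xt - a[nz] * yt;
    y[t] = yt;
  }
  return y;
}
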