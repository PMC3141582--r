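#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 4-point regularized delta kernel (dimensionless argument)
static inline double phi4(double r) {
  double a = std::fabs(r);
  if (a >= 2.0) return 0.0;
  if (a <= 1.0) return (3.0 - 2.0 * a + std::sqrt(1.0 + 4.0 * a - 4.0 * a * a)) / 8.0;
  return (5.0 - 2.0 * a - std::sqrt(-7.0 + 12.0 * a - 4.0 * a * a)) / 8.0;
}

// [[Rcpp::export]]
NumericVector phi4_cpp(NumericVector r) {
  int n = r.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = phi4(r[i]);
  return out;
}

// accumulate val into a length-M vector at (1-based) positions idx
// [[Rcpp::export]]
NumericVector acc_add_cpp(IntegerVector idx, NumericVector val, int M) {
  NumericVector out(M);
  int n = idx.size();
  for (int i = 0; i < n; ++i) out[idx[i] - 1] += val[i];
  return out;
}

static inline int wrap(int i, int n) {
  int m = i % n;
  return m < 0 ? m + n : m;
}

// stencil base index and 4 weights for coordinate x on cell-centered
// periodic grid (nodes at (i+0.5)h)
static inline void stencil1d(double x, double h, int n, int *base, double *w) {
  double s = x / h - 0.5;           // node-index coordinate
  int i0 = (int)std::floor(s) - 1;  // leftmost of the 4 support nodes
  for (int a = 0; a < 4; ++a) w[a] = phi4(s - (i0 + a));
  *base = i0;
}

// [[Rcpp::export]]
List spread_2d(NumericMatrix X, NumericMatrix F, NumericVector ds,
               IntegerVector n, double h) {
  int nx = n[0], ny = n[1];
  NumericMatrix fx(nx, ny), fy(nx, ny);
  double inv = 1.0 / (h * h);
  int M = X.nrow();
  int bi, bj;
  double wx[4], wy[4];
  for (int m = 0; m < M; ++m) {
    if (!std::isfinite(X(m, 0)) || !std::isfinite(X(m, 1)))
      stop("non-finite boundary point %d (blow-up upstream?)", m + 1);
    stencil1d(X(m, 0), h, nx, &bi, wx);
    stencil1d(X(m, 1), h, ny, &bj, wy);
    double cx = F(m, 0) * ds[m] * inv, cy = F(m, 1) * ds[m] * inv;
    for (int a = 0; a < 4; ++a) {
      int i = wrap(bi + a, nx);
      for (int b = 0; b < 4; ++b) {
        int j = wrap(bj + b, ny);
        double w = wx[a] * wy[b];
        fx(i, j) += cx * w;
        fy(i, j) += cy * w;
      }
    }
  }
  return List::create(fx, fy);
}

// [[Rcpp::export]]
NumericMatrix interp_2d(NumericMatrix ux, NumericMatrix uy, NumericMatrix X,
                        IntegerVector n, double h) {
  int nx = n[0], ny = n[1];
  int M = X.nrow();
  NumericMatrix U(M, 2);
  int bi, bj;
  double wx[4], wy[4];
  for (int m = 0; m < M; ++m) {
    stencil1d(X(m, 0), h, nx, &bi, wx);
    stencil1d(X(m, 1), h, ny, &bj, wy);
    double sx = 0.0, sy = 0.0;
    for (int a = 0; a < 4; ++a) {
      int i = wrap(bi + a, nx);
      for (int b = 0; b < 4; ++b) {
        int j = wrap(bj + b, ny);
        double w = wx[a] * wy[b];
        sx += ux(i, j) * w;
        sy += uy(i, j) * w;
      }
    }
    U(m, 0) = sx;
    U(m, 1) = sy;
  }
  return U;
}

// [[Rcpp::export]]
List spread_3d(NumericMatrix X, NumericMatrix F, NumericVector ds,
               IntegerVector n, double h) {
  int nx = n[0], ny = n[1], nz = n[2];
  NumericVector fx(nx * ny * nz), fy(nx * ny * nz), fz(nx * ny * nz);
  double inv = 1.0 / (h * h * h);
  int M = X.nrow();
  int bi, bj, bk;
  double wx[4], wy[4], wz[4];
  for (int m = 0; m < M; ++m) {
    if (!std::isfinite(X(m, 0)) || !std::isfinite(X(m, 1)) || !std::isfinite(X(m, 2)))
      stop("non-finite boundary point %d (blow-up upstream?)", m + 1);
    stencil1d(X(m, 0), h, nx, &bi, wx);
    stencil1d(X(m, 1), h, ny, &bj, wy);
    stencil1d(X(m, 2), h, nz, &bk, wz);
    double cx = F(m, 0) * ds[m] * inv, cy = F(m, 1) * ds[m] * inv, cz = F(m, 2) * ds[m] * inv;
    for (int a = 0; a < 4; ++a) {
      int i = wrap(bi + a, nx);
      for (int b = 0; b < 4; ++b) {
        int j = wrap(bj + b, ny);
        double wab = wx[a] * wy[b];
        for (int c = 0; c < 4; ++c) {
          int k = wrap(bk + c, nz);
          double w = wab * wz[c];
          int idx = i + nx * (j + ny * k);
          fx[idx] += cx * w;
          fy[idx] += cy * w;
          fz[idx] += cz * w;
        }
      }
    }
  }
  fx.attr("dim") = n; fy.attr("dim") = n; fz.attr("dim") = n;
  return List::create(fx, fy, fz);
}

// [[Rcpp::export]]
NumericMatrix interp_3d(NumericVector ux, NumericVector uy, NumericVector uz,
                        NumericMatrix X, IntegerVector n, double h) {
  int nx = n[0], ny = n[1], nz = n[2];
  int M = X.nrow();
  NumericMatrix U(M, 3);
  int bi, bj, bk;
  double wx[4], wy[4], wz[4];
  for (int m = 0; m < M; ++m) {
    stencil1d(X(m, 0), h, nx, &bi, wx);
    stencil1d(X(m, 1), h, ny, &bj, wy);
    stencil1d(X(m, 2), h, nz, &bk, wz);
    double sx = 0.0, sy = 0.0, sz = 0.0;
    for (int a = 0; a < 4; ++a) {
      int i = wrap(bi + a, nx);
      for (int b = 0; b < 4; ++b) {
        int j = wrap(bj + b, ny);
        double wab = wx[a] * wy[b];
        for (int c = 0; c < 4; ++c) {
          int k = wrap(bk + c, nz);
          double w = wab * wz[c];
          int idx = i + nx * (j + ny * k);
          sx += ux[idx] * w;
          sy += uy[idx] * w;
          sz += uz[idx] * w;
        }
      }
    }
    U(m, 0) = sx;
    U(m, 1) = sy;
    U(m, 2) = sz;
  }
  return U;
}
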