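// Dense image interpolation: B-spline prefiltering (Unser-style recursive
// filters), warping by a dense displacement field, and bilinear resizing.
// Images are R matrices indexed (row, col) = (y, x); displacements are in
// pixels with pull/backward-warp semantics: out(x) = img(x + d(x)).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double POLES3[] = { -0.2679491924311227 };          // sqrt(3)-2
static const double POLES5[] = { -0.4305753470999738,
                                 -0.0430962882032647 };

// one-sided power B-spline kernel of odd order n (support (-(n+1)/2,(n+1)/2))
static inline double bspline_kernel(int n, double x) {
  const double half = 0.5 * (n + 1);
  if (std::fabs(x) >= half) return 0.0;
  double fact = 1.0;
  for (int k = 2; k <= n; ++k) fact *= k;
  double v = 0.0, binom = 1.0;
  for (int k = 0; k <= n + 1; ++k) {
    double t = x + half - k;
    if (t > 0.0) {
      double p = 1.0;
      for (int j = 0; j < n; ++j) p *= t;
      v += (k % 2 ? -binom : binom) * p;
    }
    binom = binom * (n + 1 - k) / (k + 1);
  }
  return v / fact;
}

static double initial_causal(const double* c, int n, int stride, double z,
                             double tol) {
  int horizon = n;
  if (tol > 0.0) {
    int h = (int)std::ceil(std::log(tol) / std::log(std::fabs(z)));
    if (h < horizon) horizon = h;
  }
  if (horizon < n) {
    double zk = z, sum = c[0];
    for (int k = 1; k < horizon; ++k) { sum += zk * c[k * stride]; zk *= z; }
    return sum;
  }
  // full mirror-boundary loop
  double zk = z, z2n = std::pow(z, n - 1), sum;
  sum = c[0] + z2n * c[(n - 1) * stride];
  z2n *= z2n * (1.0 / z);
  for (int k = 1; k <= n - 2; ++k) {
    sum += (zk + z2n) * c[k * stride];
    zk *= z; z2n *= 1.0 / z;
  }
  return sum / (1.0 - std::pow(z, 2 * n - 2));
}

static void filter_line(double* c, int n, int stride, const double* poles,
                        int npoles) {
  if (n == 1) return;
  double gain = 1.0;
  for (int p = 0; p < npoles; ++p)
    gain *= (1.0 - poles[p]) * (1.0 - 1.0 / poles[p]);
  for (int k = 0; k < n; ++k) c[k * stride] *= gain;
  for (int p = 0; p < npoles; ++p) {
    const double z = poles[p];
    c[0] = initial_causal(c, n, stride, z, 1e-12);
    for (int k = 1; k < n; ++k) c[k * stride] += z * c[(k - 1) * stride];
    c[(n - 1) * stride] = (z / (z * z - 1.0)) *
      (c[(n - 1) * stride] + z * c[(n - 2) * stride]);
    for (int k = n - 2; k >= 0; --k)
      c[k * stride] = z * (c[(k + 1) * stride] - c[k * stride]);
  }
}

// [[Rcpp::export(name = ".cpp_bspline_prefilter")]]
NumericMatrix cpp_bspline_prefilter(NumericMatrix img, int order) {
  NumericMatrix out = clone(img);
  if (order < 2) return out;
  const double* poles = (order == 3) ? POLES3 : POLES5;
  int npoles = (order == 3) ? 1 : 2;
  if (order != 3 && order != 5) stop("prefilter supports orders 3 and 5");
  int nr = out.nrow(), nc = out.ncol();
  double* ptr = out.begin();
  for (int j = 0; j < nc; ++j)            // along columns (y)
    filter_line(ptr + (size_t)j * nr, nr, 1, poles, npoles);
  for (int i = 0; i < nr; ++i)            // along rows (x)
    filter_line(ptr + i, nc, nr, poles, npoles);
  return out;
}

static inline int mirror_index(int k, int n) {
  if (n == 1) return 0;
  const int period = 2 * n - 2;
  k = std::abs(k) % period;
  return (k >= n) ? period - k : k;
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static double sample_spline(const double* coef, int nr, int nc, double y,
                            double x, int order) {
  const int half = (order + 1) / 2;
  int iy = (int)std::floor(y), ix = (int)std::floor(x);
  double wy[6], wx[6];
  int ky0 = iy - half + 1, kx0 = ix - half + 1;
  for (int k = 0; k < order + 1; ++k) {
    wy[k] = bspline_kernel(order, y - (ky0 + k));
    wx[k] = bspline_kernel(order, x - (kx0 + k));
  }
  double v = 0.0;
  for (int ky = 0; ky < order + 1; ++ky) {
    int yy = mirror_index(ky0 + ky, nr);
    double row = 0.0;
    for (int kx = 0; kx < order + 1; ++kx) {
      int xx = mirror_index(kx0 + kx, nc);
      row += wx[kx] * coef[(size_t)xx * nr + yy];
    }
    v += wy[ky] * row;
  }
  return v;
}

static double sample_linear(const double* img, int nr, int nc, double y,
                            double x) {
  int i0 = (int)std::floor(y), j0 = (int)std::floor(x);
  if (i0 >= nr - 1) i0 = nr - 2; if (i0 < 0) i0 = 0;
  if (j0 >= nc - 1) j0 = nc - 2; if (j0 < 0) j0 = 0;
  double fy = y - i0, fx = x - j0;
  const double* c0 = img + (size_t)j0 * nr;
  const double* c1 = img + (size_t)(j0 + 1 < nc ? j0 + 1 : j0) * nr;
  int i1 = i0 + 1 < nr ? i0 + 1 : i0;
  return (1 - fy) * ((1 - fx) * c0[i0] + fx * c1[i0]) +
         fy * ((1 - fx) * c0[i1] + fx * c1[i1]);
}

// [[Rcpp::export(name = ".cpp_warp")]]
NumericMatrix cpp_warp(NumericMatrix img, NumericMatrix dy, NumericMatrix dx,
                       int order) {
  int nr = img.nrow(), nc = img.ncol();
  if (dy.nrow() != nr || dy.ncol() != nc || dx.nrow() != nr ||
      dx.ncol() != nc)
    stop("displacement field shape must match image shape");
  NumericMatrix out(nr, nc);
  NumericMatrix coef;
  if (order >= 2) coef = cpp_bspline_prefilter(img, order);
  const double* src = (order >= 2) ? coef.begin() : img.begin();
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double y = clampd(i + dy(i, j), 0.0, nr - 1.0);
      double x = clampd(j + dx(i, j), 0.0, nc - 1.0);
      double v;
      if (order == 0)
        v = img((int)std::lround(y), (int)std::lround(x));
      else if (order == 1)
        v = sample_linear(src, nr, nc, y, x);
      else
        v = sample_spline(src, nr, nc, y, x, order);
      out(i, j) = v;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_resize_bilinear")]]
NumericMatrix cpp_resize_bilinear(NumericMatrix img, int nr2, int nc2) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr2, nc2);
  double sy = (nr2 > 1) ? (double)(nr - 1) / (nr2 - 1) : 0.0;
  double sx = (nc2 > 1) ? (double)(nc - 1) / (nc2 - 1) : 0.0;
  for (int j = 0; j < nc2; ++j)
    for (int i = 0; i < nr2; ++i)
      out(i, j) = sample_linear(img.begin(), nr, nc, i * sy, j * sx);
  return out;
}
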