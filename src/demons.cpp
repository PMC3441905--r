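// Demons/optical-flow inner loop at one pyramid level.  Kept in C++ because
// it runs tens of iterations of warp + gradient + smooth per level.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

NumericMatrix cpp_gauss_smooth(NumericMatrix img, double sigma);

static void gradient(const NumericMatrix& img, NumericMatrix& gy,
                     NumericMatrix& gx) {
  int nr = img.nrow(), nc = img.ncol();
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int ip = i + 1 < nr ? i + 1 : i, im = i > 0 ? i - 1 : i;
      int jp = j + 1 < nc ? j + 1 : j, jm = j > 0 ? j - 1 : j;
      gy(i, j) = 0.5 * (img(ip, j) - img(im, j));
      gx(i, j) = 0.5 * (img(i, jp) - img(i, jm));
    }
}

static inline double bilinear(const double* img, int nr, int nc, double y,
                              double x) {
  if (y < 0) y = 0; if (y > nr - 1) y = nr - 1;
  if (x < 0) x = 0; if (x > nc - 1) x = nc - 1;
  int i0 = (int)y, j0 = (int)x;
  if (i0 >= nr - 1) i0 = nr - 2; if (i0 < 0) i0 = 0;
  if (j0 >= nc - 1) j0 = nc - 2; if (j0 < 0) j0 = 0;
  double fy = y - i0, fx = x - j0;
  int i1 = i0 + 1 < nr ? i0 + 1 : i0, j1 = j0 + 1 < nc ? j0 + 1 : j0;
  const double* c0 = img + (size_t)j0 * nr;
  const double* c1 = img + (size_t)j1 * nr;
  return (1 - fy) * ((1 - fx) * c0[i0] + fx * c1[i0]) +
         fy * ((1 - fx) * c0[i1] + fx * c1[i1]);
}

// [[Rcpp::export(name = ".cpp_demons_level")]]
List cpp_demons_level(NumericMatrix moving, NumericMatrix fixed,
                      NumericMatrix dy0, NumericMatrix dx0,
                      double sigma_field, double sigma_fluid, int max_iter,
                      double tol, double step_cap) {
  int nr = fixed.nrow(), nc = fixed.ncol();
  NumericMatrix dy = clone(dy0), dx = clone(dx0);
  NumericMatrix gfy(nr, nc), gfx(nr, nc), gwy(nr, nc), gwx(nr, nc);
  NumericMatrix w(nr, nc), uy(nr, nc), ux(nr, nc);
  gradient(fixed, gfy, gfx);
  double mean_u = 0.0;
  for (int it = 0; it < max_iter; ++it) {
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i)
        w(i, j) = bilinear(moving.begin(), nr, nc, i + dy(i, j), j + dx(i, j));
    gradient(w, gwy, gwx);
    double usum = 0.0;
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        double diff = fixed(i, j) - w(i, j);
        double gy = 0.5 * (gfy(i, j) + gwy(i, j));
        double gx = 0.5 * (gfx(i, j) + gwx(i, j));
        double denom = gy * gy + gx * gx + diff * diff;
        double s = denom > 1e-9 ? diff / denom : 0.0;
        double vy = s * gy, vx = s * gx;
        double mag = std::sqrt(vy * vy + vx * vx);
        if (mag > step_cap) { vy *= step_cap / mag; vx *= step_cap / mag; }
        uy(i, j) = vy; ux(i, j) = vx;
        usum += mag > step_cap ? step_cap : mag;
      }
    uy = cpp_gauss_smooth(uy, sigma_fluid);
    ux = cpp_gauss_smooth(ux, sigma_fluid);
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) { dy(i, j) += uy(i, j); dx(i, j) += ux(i, j); }
    dy = cpp_gauss_smooth(dy, sigma_field);
    dx = cpp_gauss_smooth(dx, sigma_field);
    mean_u = usum / (nr * nc);
    if (mean_u < tol) break;
  }
  return List::create(_["dy"] = dy, _["dx"] = dx, _["mean_update"] = mean_u);
}
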