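// Pixel-wise three-parameter magnitude inversion-recovery fitting:
// minimize sum_i (s_i - |A - B exp(-TI_i / T1*)|)^2 by multi-start
// downhill simplex (Nelder-Mead).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double molli_rss(const double* th, const double* s,
                               const double* ti, int n) {
  const double A = th[0], B = th[1], T1s = th[2];
  if (!(T1s >= 1.0) || T1s > 2e4) return 1e30 + (T1s < 1.0 ? 1.0 - T1s : T1s);
  double rss = 0.0;
  for (int i = 0; i < n; ++i) {
    double m = std::fabs(A - B * std::exp(-ti[i] / T1s));
    double d = s[i] - m;
    rss += d * d;
  }
  return rss;
}

// standard Nelder-Mead on 3 parameters
static double nelder_mead(double* x, const double* s, const double* ti,
                          int n, int maxit) {
  const int d = 3;
  double simplex[4][3], fv[4];
  double step[3] = { 0.1 * std::fabs(x[0]) + 1e-3,
                     0.1 * std::fabs(x[1]) + 1e-3,
                     0.3 * std::fabs(x[2]) + 1.0 };
  for (int v = 0; v <= d; ++v) {
    for (int k = 0; k < d; ++k)
      simplex[v][k] = x[k] + (v == k + 1 ? step[k] : 0.0);
    fv[v] = molli_rss(simplex[v], s, ti, n);
  }
  for (int iter = 0; iter < maxit; ++iter) {
    // order: lo = best, hi = worst, nh = next worst
    int lo = 0, hi = 0, nh = 0;
    for (int v = 1; v <= d; ++v) {
      if (fv[v] < fv[lo]) lo = v;
      if (fv[v] > fv[hi]) hi = v;
    }
    for (int v = 0; v <= d; ++v)
      if (v != hi && fv[v] > fv[nh]) nh = v;
    if (fv[hi] - fv[lo] <= 1e-14 + 1e-12 * std::fabs(fv[lo])) break;
    double cen[3] = { 0, 0, 0 };
    for (int v = 0; v <= d; ++v)
      if (v != hi)
        for (int k = 0; k < d; ++k) cen[k] += simplex[v][k] / d;
    double xr[3], xe[3], xc[3];
    for (int k = 0; k < d; ++k) xr[k] = cen[k] + (cen[k] - simplex[hi][k]);
    double fr = molli_rss(xr, s, ti, n);
    if (fr < fv[lo]) {
      for (int k = 0; k < d; ++k)
        xe[k] = cen[k] + 2.0 * (cen[k] - simplex[hi][k]);
      double fe = molli_rss(xe, s, ti, n);
      if (fe < fr) {
        for (int k = 0; k < d; ++k) simplex[hi][k] = xe[k];
        fv[hi] = fe;
      } else {
        for (int k = 0; k < d; ++k) simplex[hi][k] = xr[k];
        fv[hi] = fr;
      }
    } else if (fr < fv[nh]) {
      for (int k = 0; k < d; ++k) simplex[hi][k] = xr[k];
      fv[hi] = fr;
    } else {
      for (int k = 0; k < d; ++k)
        xc[k] = cen[k] + 0.5 * (simplex[hi][k] - cen[k]);
      double fc = molli_rss(xc, s, ti, n);
      if (fc < fv[hi]) {
        for (int k = 0; k < d; ++k) simplex[hi][k] = xc[k];
        fv[hi] = fc;
      } else {                          // shrink toward best
        for (int v = 0; v <= d; ++v) {
          if (v == lo) continue;
          for (int k = 0; k < d; ++k)
            simplex[v][k] = simplex[lo][k] +
              0.5 * (simplex[v][k] - simplex[lo][k]);
          fv[v] = molli_rss(simplex[v], s, ti, n);
        }
      }
    }
  }
  int lo = 0;
  for (int v = 1; v <= 3; ++v)
    if (fv[v] < fv[lo]) lo = v;
  for (int k = 0; k < d; ++k) x[k] = simplex[lo][k];
  return fv[lo];
}

// coarse T1* scan: at each candidate T1* solve for (A, B) by a few
// sign-iterated linear least-squares passes of the magnitude model; the
// best candidate seeds an extra simplex start so the multimodal landscape
// near signal nulls cannot trap the fit
// writes the `k_out` best candidates (each a triple A, B, T1*) into
// x_out[3 * k_out]; candidates are local minima of rss along the scan
static void coarse_scan(const double* s, const double* ti, int n,
                        double* x_out, int k_out) {
  std::vector<double> cand;     // (rss, A, B, t1) quadruples
  for (double t1 = 50.0; t1 <= 3200.0; t1 += 25.0) {
    double A = 0.0, B = 0.0;
    for (int i = 0; i < n; ++i) if (s[i] > A) A = s[i];
    B = 2.0 * A;
    for (int pass = 0; pass < 4; ++pass) {
      double n11 = 0, n12 = 0, n22 = 0, b1 = 0, b2 = 0;
      for (int i = 0; i < n; ++i) {
        double e = std::exp(-ti[i] / t1);
        double sg = (A - B * e) >= 0 ? 1.0 : -1.0;
        double y = sg * s[i];
        n11 += 1.0;  n12 += -e;  n22 += e * e;
        b1 += y;     b2 += -e * y;
      }
      double det = n11 * n22 - n12 * n12;
      if (std::fabs(det) < 1e-12) break;
      A = (b1 * n22 - n12 * b2) / det;
      B = (n11 * b2 - n12 * b1) / det;
    }
    double th[3] = { A, B, t1 };
    double r = molli_rss(th, s, ti, n);
    cand.push_back(r); cand.push_back(A); cand.push_back(B); cand.push_back(t1);
  }
  // pick the k_out best-scoring scan points that are not adjacent to an
  // already-chosen one (distinct basins)
  int ncand = (int)cand.size() / 4;
  std::vector<bool> used(ncand, false);
  for (int k = 0; k < k_out; ++k) {
    int best = -1;
    for (int c = 0; c < ncand; ++c) {
      if (used[c]) continue;
      if (best < 0 || cand[4 * c] < cand[4 * best]) best = c;
    }
    if (best < 0) best = 0;
    for (int c = best - 2; c <= best + 2; ++c)
      if (c >= 0 && c < ncand) used[c] = true;
    x_out[3 * k + 0] = cand[4 * best + 1];
    x_out[3 * k + 1] = cand[4 * best + 2];
    x_out[3 * k + 2] = cand[4 * best + 3];
  }
}

// signals: npix x nti matrix (one row per pixel); returns npix x 4 matrix
// with columns (A, B, T1*, rss); rows of non-finite or all-zero signal are NA.
// [[Rcpp::export(name = ".cpp_fit_molli")]]
NumericMatrix cpp_fit_molli(NumericMatrix signals, NumericVector ti,
                            NumericVector t1_starts, int maxit,
                            int n_restarts) {
  int npix = signals.nrow(), n = signals.ncol();
  if ((int)ti.size() != n) stop("length(ti) must equal ncol(signals)");
  NumericMatrix out(npix, 4);
  std::vector<double> s(n), tiv(ti.begin(), ti.end());
  for (int p = 0; p < npix; ++p) {
    bool ok = true;
    double smax = 0.0;
    for (int i = 0; i < n; ++i) {
      s[i] = signals(p, i);
      if (!std::isfinite(s[i])) { ok = false; break; }
      if (s[i] > smax) smax = s[i];
    }
    if (!ok || smax <= 0.0) {
      for (int k = 0; k < 4; ++k) out(p, k) = NA_REAL;
      continue;
    }
    double best[3] = { smax, 2.0 * smax, t1_starts[0] };
    double bestf = R_PosInf;
    for (int t = 0; t < (int)t1_starts.size(); ++t) {
      double x[3] = { smax, 2.0 * smax, t1_starts[t] };
      double f = nelder_mead(x, s.data(), tiv.data(), n, maxit);
      if (f < bestf) { bestf = f; best[0] = x[0]; best[1] = x[1]; best[2] = x[2]; }
    }
    {   // degenerate start: constant signal has its optimum at B = 0
      double x[3] = { smax, 0.0, 800.0 };
      double f = nelder_mead(x, s.data(), tiv.data(), n, maxit);
      if (f < bestf) { bestf = f; best[0] = x[0]; best[1] = x[1]; best[2] = x[2]; }
    }
    {   // coarse-scan starts (3 distinct basins)
      double xs[9];
      coarse_scan(s.data(), tiv.data(), n, xs, 3);
      for (int c = 0; c < 3; ++c) {
        double x[3] = { xs[3 * c], xs[3 * c + 1], xs[3 * c + 2] };
        double f = nelder_mead(x, s.data(), tiv.data(), n, maxit);
        if (f < bestf) { bestf = f; best[0] = x[0]; best[1] = x[1]; best[2] = x[2]; }
      }
    }
    for (int r = 0; r < n_restarts; ++r) {   // polish from the winner
      double x[3] = { best[0], best[1], best[2] };
      double f = nelder_mead(x, s.data(), tiv.data(), n, maxit);
      if (f < bestf) { bestf = f; best[0] = x[0]; best[1] = x[1]; best[2] = x[2]; }
    }
    out(p, 0) = best[0]; out(p, 1) = best[1];
    out(p, 2) = best[2]; out(p, 3) = bestf;
  }
  return out;
}
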