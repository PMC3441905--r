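// Separable Gaussian smoothing, connected-component labelling and binary
// erosion used by the registration regularizer and blood-pool segmentation.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline int reflect_index(int k, int n) {
  if (n == 1) return 0;
  while (k < 0 || k >= n) {
    if (k < 0) k = -k - 1;
    if (k >= n) k = 2 * n - k - 1;
  }
  return k;
}

// [[Rcpp::export(name = ".cpp_gauss_smooth")]]
NumericMatrix cpp_gauss_smooth(NumericMatrix img, double sigma) {
  if (sigma <= 0) return clone(img);
  int nr = img.nrow(), nc = img.ncol();
  int radius = std::max(1, (int)std::ceil(3.5 * sigma));
  std::vector<double> k(2 * radius + 1);
  double s = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + radius];
  }
  for (double& v : k) v /= s;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)          // vertical pass
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -radius; d <= radius; ++d)
        acc += k[d + radius] * img(reflect_index(i + d, nr), j);
      tmp(i, j) = acc;
    }
  for (int j = 0; j < nc; ++j)          // horizontal pass
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -radius; d <= radius; ++d)
        acc += k[d + radius] * tmp(i, reflect_index(j + d, nc));
      out(i, j) = acc;
    }
  return out;
}

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix labels(nr, nc);
  std::vector<std::pair<int, int> > nb;
  for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx) {
      if (dy == 0 && dx == 0) continue;
      if (connectivity == 4 && std::abs(dy) + std::abs(dx) != 1) continue;
      nb.push_back(std::make_pair(dy, dx));
    }
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || labels(i, j) != 0) continue;
      labels(i, j) = ++next;
      stack.push_back(std::make_pair(i, j));
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (size_t q = 0; q < nb.size(); ++q) {
          int y = p.first + nb[q].first, x = p.second + nb[q].second;
          if (y < 0 || y >= nr || x < 0 || x >= nc) continue;
          if (mask(y, x) && labels(y, x) == 0) {
            labels(y, x) = next;
            stack.push_back(std::make_pair(y, x));
          }
        }
      }
    }
  return labels;
}

// Erosion with a Euclidean disk; pixels outside the image count as
// background, so the image border is eroded too.
// [[Rcpp::export(name = ".cpp_erode_disk")]]
LogicalMatrix cpp_erode_disk(LogicalMatrix mask, double radius) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out(nr, nc);
  int r = (int)std::floor(radius);
  std::vector<std::pair<int, int> > se;
  for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx)
      if (dy * dy + dx * dx <= radius * radius + 1e-9)
        se.push_back(std::make_pair(dy, dx));
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) { out(i, j) = FALSE; continue; }
      bool keep = true;
      for (size_t q = 0; q < se.size() && keep; ++q) {
        int y = i + se[q].first, x = j + se[q].second;
        if (y < 0 || y >= nr || x < 0 || x >= nc || !mask(y, x)) keep = false;
      }
      out(i, j) = keep;
    }
  return out;
}
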