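#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Grayscale morphology and raster utilities for AFM height maps.
// Conventions: matrices are R numeric matrices (column-major), heights in nm.
// The structuring function `se` is a (2k+1)x(2k+1) matrix with the tip apex
// at the centre; entries are <= 0 (tip opens downward), NA marks pixels
// outside the tip support. Pixels outside the image are ignored (treated as
// -Inf for dilation, +Inf for erosion), which preserves the global maximum
// of interior features.

// [[Rcpp::export]]
NumericMatrix grey_dilate_cpp(const NumericMatrix& f, const NumericMatrix& se) {
  const int nr = f.nrow(), nc = f.ncol();
  const int kr = (se.nrow() - 1) / 2, kc = (se.ncol() - 1) / 2;
  NumericMatrix g(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double best = R_NegInf;
      const int i0 = std::max(0, i - kr), i1 = std::min(nr - 1, i + kr);
      const int j0 = std::max(0, j - kc), j1 = std::min(nc - 1, j + kc);
      for (int jj = j0; jj <= j1; ++jj) {
        for (int ii = i0; ii <= i1; ++ii) {
          const double s = se(ii - i + kr, jj - j + kc);
          if (ISNA(s)) continue;
          const double v = f(ii, jj) + s;
          if (v > best) best = v;
        }
      }
      g(i, j) = best;
    }
  }
  return g;
}

// [[Rcpp::export]]
NumericMatrix grey_erode_cpp(const NumericMatrix& f, const NumericMatrix& se) {
  const int nr = f.nrow(), nc = f.ncol();
  const int kr = (se.nrow() - 1) / 2, kc = (se.ncol() - 1) / 2;
  NumericMatrix g(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double best = R_PosInf;
      const int i0 = std::max(0, i - kr), i1 = std::min(nr - 1, i + kr);
      const int j0 = std::max(0, j - kc), j1 = std::min(nc - 1, j + kc);
      for (int jj = j0; jj <= j1; ++jj) {
        for (int ii = i0; ii <= i1; ++ii) {
          const double s = se(ii - i + kr, jj - j + kc);
          if (ISNA(s)) continue;
          const double v = f(ii, jj) - s;
          if (v < best) best = v;
        }
      }
      g(i, j) = best;
    }
  }
  return g;
}

// Connected-component labelling of a logical mask, 8-connectivity,
// iterative flood fill. Labels are 1..n in scan order of first pixel.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pi = p % nr, pj = p / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            const int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
            if (mask(qi, qj) && lab(qi, qj) == 0) {
              lab(qi, qj) = next;
              stack.push_back(qi + qj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

static inline int nbr(const IntegerMatrix& m, int i, int j) {
  if (i < 0 || i >= m.nrow() || j < 0 || j >= m.ncol()) return 0;
  return m(i, j);
}

// Zhang-Suen thinning of a binary mask down to a ~1 px, 8-connected skeleton.
// [[Rcpp::export]]
LogicalMatrix thin_mask_cpp(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix img(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) img(i, j) = mask(i, j) ? 1 : 0;
  bool changed = true;
  std::vector<int> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!img(i, j)) continue;
          // neighbours P2..P9 clockwise from north (row-1)
          const int p2 = nbr(img, i - 1, j),     p3 = nbr(img, i - 1, j + 1);
          const int p4 = nbr(img, i, j + 1),     p5 = nbr(img, i + 1, j + 1);
          const int p6 = nbr(img, i + 1, j),     p7 = nbr(img, i + 1, j - 1);
          const int p8 = nbr(img, i, j - 1),     p9 = nbr(img, i - 1, j - 1);
          const int b = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (b < 2 || b > 6) continue;
          int a = 0;
          const int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          for (int k = 0; k < 8; ++k) if (seq[k] == 0 && seq[k + 1] == 1) ++a;
          if (a != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(i + j * nr);
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t k = 0; k < kill.size(); ++k)
          img(kill[k] % nr, kill[k] / nr) = 0;
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) out(i, j) = img(i, j) == 1;
  return out;
}

// Render swept-sphere ("tube") profiles: for each sample point k at physical
// (x[k], y[k]) nm with local radius r[k] nm sitting on support s[k] nm, the
// visible upper envelope is s + r + sqrt(r^2 - rho^2) for rho <= r (rho =
// lateral distance to the sample). The grid is updated in place with the
// pointwise max (upper-envelope composition). x = col centre * px, y = row
// centre * px (0-based pixel centres).
// [[Rcpp::export]]
NumericMatrix stamp_tubes_cpp(NumericMatrix grid, double px,
                              const NumericVector& x, const NumericVector& y,
                              const NumericVector& r, const NumericVector& s) {
  const int nr = grid.nrow(), nc = grid.ncol();
  const int n = x.size();
  for (int k = 0; k < n; ++k) {
    const double rk = r[k];
    if (!(rk > 0)) continue;
    const int j0 = std::max(0, (int)std::floor((x[k] - rk) / px));
    const int j1 = std::min(nc - 1, (int)std::ceil((x[k] + rk) / px));
    const int i0 = std::max(0, (int)std::floor((y[k] - rk) / px));
    const int i1 = std::min(nr - 1, (int)std::ceil((y[k] + rk) / px));
    for (int j = j0; j <= j1; ++j) {
      const double dx = j * px - x[k];
      for (int i = i0; i <= i1; ++i) {
        const double dy = i * px - y[k];
        const double rho2 = dx * dx + dy * dy;
        if (rho2 > rk * rk) continue;
        const double h = s[k] + rk + std::sqrt(rk * rk - rho2);
        if (h > grid(i, j)) grid(i, j) = h;
      }
    }
  }
  return grid;
}

// Bilinear interpolation of heights at physical coordinates (nm).
// Points outside the grid return NA.
// [[Rcpp::export]]
NumericVector bilinear_cpp(const NumericMatrix& f, double px,
                           const NumericVector& x, const NumericVector& y) {
  const int nr = f.nrow(), nc = f.ncol();
  const int n = x.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    const double cx = x[k] / px, cy = y[k] / px;
    if (cx < 0 || cy < 0 || cx > nc - 1 || cy > nr - 1) {
      out[k] = NA_REAL; continue;
    }
    int j = (int)std::floor(cx), i = (int)std::floor(cy);
    if (j >= nc - 1) j = nc - 2;
    if (i >= nr - 1) i = nr - 2;
    const double tx = cx - j, ty = cy - i;
    out[k] = f(i, j) * (1 - tx) * (1 - ty) + f(i, j + 1) * tx * (1 - ty) +
             f(i + 1, j) * (1 - tx) * ty + f(i + 1, j + 1) * tx * ty;
  }
  return out;
}

static inline double cr_spline(double p0, double p1, double p2, double p3, double t) {
  // Catmull-Rom: interpolates p1..p2 for t in [0,1]
  return p1 + 0.5 * t * (p2 - p0 + t * (2.0 * p0 - 5.0 * p1 + 4.0 * p2 - p3 +
         t * (3.0 * (p1 - p2) + p3 - p0)));
}

// Bicubic (Catmull-Rom) interpolation of heights at physical coords (nm).
// Reconstructs smooth maxima (particle domes) without the systematic
// depression of bilinear sampling. Falls back to clamped indices at the
// borders; points outside the grid return NA.
// [[Rcpp::export]]
NumericVector bicubic_cpp(const NumericMatrix& f, double px,
                          const NumericVector& x, const NumericVector& y) {
  const int nr = f.nrow(), nc = f.ncol();
  const int n = x.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    const double cx = x[k] / px, cy = y[k] / px;
    if (cx < 0 || cy < 0 || cx > nc - 1 || cy > nr - 1) {
      out[k] = NA_REAL; continue;
    }
    int j = (int)std::floor(cx), i = (int)std::floor(cy);
    if (j >= nc - 1) j = nc - 2;
    if (i >= nr - 1) i = nr - 2;
    const double tx = cx - j, ty = cy - i;
    double col[4];
    for (int m = -1; m <= 2; ++m) {
      const int jj = std::min(std::max(j + m, 0), nc - 1);
      const int i0 = std::max(i - 1, 0), i1 = i, i2 = i + 1,
                i3 = std::min(i + 2, nr - 1);
      col[m + 1] = cr_spline(f(i0, jj), f(i1, jj), f(i2, jj), f(i3, jj), ty);
    }
    out[k] = cr_spline(col[0], col[1], col[2], col[3], tx);
  }
  return out;
}
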