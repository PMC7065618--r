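#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// 26-connected (or 6-connected) component labeling of a binary volume.
// Returns 0 for background and labels 1..k in first-encounter order
// (scan order z fastest, then y, then x), which is deterministic.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const size_t n = (size_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<int> off;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int ad = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && ad != 1) continue;
        off.push_back(dz); off.push_back(dy); off.push_back(dx);
      }
  int nlab = 0;
  std::vector<size_t> stack;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        size_t i = z + (size_t)nz * (y + (size_t)ny * x);
        if (!mask[i] || lab[i]) continue;
        ++nlab;
        lab[i] = nlab;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          size_t cur = stack.back(); stack.pop_back();
          int cz = cur % nz;
          int cy = (cur / nz) % ny;
          int cx = cur / ((size_t)nz * ny);
          for (size_t o = 0; o < off.size(); o += 3) {
            int zz = cz + off[o], yy = cy + off[o + 1], xx = cx + off[o + 2];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            size_t j = zz + (size_t)nz * (yy + (size_t)ny * xx);
            if (mask[j] && !lab[j]) { lab[j] = nlab; stack.push_back(j); }
          }
        }
      }
  lab.attr("n_components") = nlab;
  return lab;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) with grid step w
static void dt1d(std::vector<double> &f, std::vector<double> &d, int n, double w,
                 std::vector<int> &v, std::vector<double> &z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double qq = q * w;
    double s;
    while (true) {
      double vv = v[k] * w;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * (qq - vv));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = q * w;
    while (z[k + 1] < qq) ++k;
    double vv = v[k] * w;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

// Anisotropic Euclidean distance (physical units) from every voxel to the
// nearest voxel of `target` (distance 0 inside the target set).
// [[Rcpp::export]]
NumericVector dist_to_set_cpp(LogicalVector target, IntegerVector dims,
                              NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const size_t n = (size_t)nz * ny * nx;
  const double BIG = 1e20;
  std::vector<double> d(n);
  for (size_t i = 0; i < n; ++i) d[i] = target[i] ? 0.0 : BIG;
  const int dimv[3] = {nz, ny, nx};
  const size_t stride[3] = {1, (size_t)nz, (size_t)nz * ny};
  int maxn = std::max(nz, std::max(ny, nx));
  std::vector<double> f(maxn), out1(maxn), zbuf(maxn + 1);
  std::vector<int> vbuf(maxn);
  for (int axis = 0; axis < 3; ++axis) {
    int na = dimv[axis];
    if (na == 1) continue;
    size_t sa = stride[axis];
    int b1 = (axis == 0) ? 1 : 0;
    int b2 = (axis == 2) ? 1 : 2;
    for (int i2 = 0; i2 < dimv[b2]; ++i2)
      for (int i1 = 0; i1 < dimv[b1]; ++i1) {
        size_t base = stride[b1] * i1 + stride[b2] * i2;
        for (int i = 0; i < na; ++i) f[i] = d[base + sa * i];
        dt1d(f, out1, na, spacing[axis], vbuf, zbuf);
        for (int i = 0; i < na; ++i) d[base + sa * i] = out1[i];
      }
  }
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = std::sqrt(d[i]);
  return out;
}

// Fill 2D-enclosed background regions ("lumina") per cross-sectional slice,
// for both orthogonal plane families: (z,y) slices at fixed x and (z,x)
// slices at fixed y. A background region is filled when it touches no slice
// border and has at most max_hole_px pixels. 4-connected background.
// [[Rcpp::export]]
IntegerVector fill_lumen_cpp(IntegerVector mask, IntegerVector dims,
                             int max_hole_px) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  IntegerVector out = clone(mask);
  std::vector<int> lab;
  std::vector<int> stack;
  auto do_planes = [&](int along) {
    int n1 = nz;                       // rows: always z
    int n2 = (along == 2) ? nx : ny;   // cols: x for fixed-y, y for fixed-x
    int n3 = (along == 2) ? ny : nx;   // slice count
    lab.assign((size_t)n1 * n2, 0);
    auto at = [&](int i1, int i2, int i3) -> int& {
      if (along == 2) return out[i1 + (size_t)nz * (i3 + (size_t)ny * i2)];
      return out[i1 + (size_t)nz * (i2 + (size_t)ny * i3)];
    };
    for (int s = 0; s < n3; ++s) {
      std::fill(lab.begin(), lab.end(), 0);
      int nlab = 0;
      std::vector<int> sizes(1, 0);
      std::vector<char> touches(1, 0);
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1; ++i) {
          if (at(i, j, s) != 0 || lab[i + (size_t)n1 * j] != 0) continue;
          ++nlab;
          sizes.push_back(0);
          touches.push_back(0);
          stack.clear();
          stack.push_back(i + n1 * j);
          lab[i + (size_t)n1 * j] = nlab;
          while (!stack.empty()) {
            int cur = stack.back(); stack.pop_back();
            int ci = cur % n1, cj = cur / n1;
            sizes[nlab]++;
            if (ci == 0 || ci == n1 - 1 || cj == 0 || cj == n2 - 1)
              touches[nlab] = 1;
            const int d1[4] = {1, -1, 0, 0}, d2[4] = {0, 0, 1, -1};
            for (int k = 0; k < 4; ++k) {
              int ii = ci + d1[k], jj = cj + d2[k];
              if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2) continue;
              if (at(ii, jj, s) != 0 || lab[ii + (size_t)n1 * jj] != 0)
                continue;
              lab[ii + (size_t)n1 * jj] = nlab;
              stack.push_back(ii + n1 * jj);
            }
          }
        }
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1; ++i) {
          int l = lab[i + (size_t)n1 * j];
          if (l > 0 && !touches[l] && sizes[l] <= max_hole_px)
            at(i, j, s) = 1;
        }
    }
  };
  do_planes(1);  // (z,y) slices at fixed x
  do_planes(2);  // (z,x) slices at fixed y
  return out;
}
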