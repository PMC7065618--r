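#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Volumes are R arrays with dim = c(nz, ny, nx); linear index z + nz*(y + ny*x).

int reflect_idx(int i, int n) {
  // symmetric half-sample reflection: -1 -> 0, n -> n-1
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericVector median3d_cpp(NumericVector vol, IntegerVector dims, int k) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int r = k / 2;
  const double *v = vol.begin();
  NumericVector out(vol.size());
  std::vector<double> buf((size_t)k * k * k);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      bool interior_xy = (x >= r && x < nx - r && y >= r && y < ny - r);
      for (int z = 0; z < nz; ++z) {
        size_t m;
        if (interior_xy && z >= r && z < nz - r) {
          // fast path: contiguous gathers, no reflection
          size_t n = 0;
          for (int dx = -r; dx <= r; ++dx)
            for (int dy = -r; dy <= r; ++dy) {
              const double *p = v + (z - r) +
                (size_t)nz * ((y + dy) + (size_t)ny * (x + dx));
              for (int dz = 0; dz < k; ++dz) buf[n++] = p[dz];
            }
          m = n / 2;
          std::nth_element(buf.begin(), buf.begin() + m, buf.begin() + n);
        } else {
          size_t n = 0;
          for (int dx = -r; dx <= r; ++dx) {
            int xx = reflect_idx(x + dx, nx);
            for (int dy = -r; dy <= r; ++dy) {
              int yy = reflect_idx(y + dy, ny);
              for (int dz = -r; dz <= r; ++dz) {
                int zz = reflect_idx(z + dz, nz);
                buf[n++] = v[zz + nz * (yy + (size_t)ny * xx)];
              }
            }
          }
          m = n / 2;
          std::nth_element(buf.begin(), buf.begin() + m, buf.begin() + n);
        }
        out[z + nz * (y + (size_t)ny * x)] = buf[m];
      }
    }
  }
  return out;
}

// separable 1D Gaussian convolution along one axis, reflected borders.
// The line is materialized with an explicit reflected pad so the inner
// loop is branch-free, and the symmetric kernel is folded (k[t] applied to
// line[i-t] + line[i+t]), halving the multiply count.
static void conv_axis(std::vector<float> &v, int nz, int ny, int nx,
                      const std::vector<float> &ker, int axis) {
  const int r = (int)ker.size() / 2;
  const int n[3] = {nz, ny, nx};
  const size_t stride[3] = {1, (size_t)nz, (size_t)nz * ny};
  const int na = n[axis];
  const size_t sa = stride[axis];
  std::vector<float> line(na + 2 * r);
  int b1 = (axis == 0) ? 1 : 0;
  int b2 = (axis == 2) ? 1 : 2;
  for (int i2 = 0; i2 < n[b2]; ++i2) {
    for (int i1 = 0; i1 < n[b1]; ++i1) {
      size_t base = stride[b1] * i1 + stride[b2] * i2;
      for (int i = -r; i < na + r; ++i)
        line[i + r] = v[base + sa * reflect_idx(i, na)];
      const float *L = line.data() + r;
      for (int i = 0; i < na; ++i) {
        float acc = ker[r] * L[i];
        for (int t = 1; t <= r; ++t)
          acc += ker[r + t] * (L[i - t] + L[i + t]);
        v[base + sa * i] = acc;
      }
    }
  }
}

void conv_axis_pub(std::vector<float> &v, int nz, int ny, int nx,
                   const std::vector<float> &ker, int axis) {
  conv_axis(v, nz, ny, nx, ker, axis);
}

static std::vector<float> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<float> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    double w = std::exp(-0.5 * i * i / (sigma * sigma));
    k[i + r] = (float)w;
    s += w;
  }
  for (auto &w : k) w = (float)(w / s);
  return k;
}

// eigenvalues of a symmetric 3x3 matrix (analytic, Cardano)
static inline void eig3(double a11, double a12, double a13, double a22,
                        double a23, double a33, double &e1, double &e2,
                        double &e3) {
  double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  if (p1 == 0.0) {
    e1 = a11; e2 = a22; e3 = a33;
  } else {
    double q = (a11 + a22 + a33) / 3.0;
    double p2 = (a11 - q) * (a11 - q) + (a22 - q) * (a22 - q) +
                (a33 - q) * (a33 - q) + 2.0 * p1;
    double p = std::sqrt(p2 / 6.0);
    double b11 = (a11 - q) / p, b22 = (a22 - q) / p, b33 = (a33 - q) / p;
    double b12 = a12 / p, b13 = a13 / p, b23 = a23 / p;
    double detB = b11 * (b22 * b33 - b23 * b23) - b12 * (b12 * b33 - b23 * b13) +
                  b13 * (b12 * b23 - b22 * b13);
    double r = detB / 2.0;
    r = std::max(-1.0, std::min(1.0, r));
    double phi = std::acos(r) / 3.0;
    e1 = q + 2.0 * p * std::cos(phi);
    e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    e2 = 3.0 * q - e1 - e3;
  }
  // sort by absolute value: |e1| <= |e2| <= |e3|
  double v[3] = {e1, e2, e3};
  std::sort(v, v + 3, [](double a, double b) { return std::fabs(a) < std::fabs(b); });
  e1 = v[0]; e2 = v[1]; e3 = v[2];
}

// Multiscale Frangi vesselness. Scales are Gaussian sigmas in the units of
// `spacing`: pass spacing = (1,1,1) for voxel-unit scales, or the physical
// voxel spacing for physically isotropic (mm) scales - on anisotropic
// grids the latter keeps the filter rotationally symmetric in space.
// cpar <= 0 requests the auto rule c = max(S)/2 with the maximum taken over
// ALL voxels and scales (a single global structureness normalizer).
// Normalizing per scale would renormalize weak off-scale responses (the
// wide halo a thin vessel casts at the largest scales) up to core strength
// before the max combination, smearing the segmentation.
// [[Rcpp::export]]
NumericVector frangi_cpp(NumericVector vol, IntegerVector dims,
                         NumericVector scales, double alpha, double beta,
                         double cpar, bool bright, NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const size_t n = (size_t)nz * ny * nx;
  const int ns = scales.size();
  NumericVector out(vol.size());
  std::vector<float> g(n);
  // geometric part (plate/blob terms) and Frobenius norm^2 per scale
  std::vector<std::vector<float>> P(ns), S2s(ns);

  auto at = [&](const std::vector<float> &v, int z, int y, int x) -> float {
    return v[reflect_idx(z, nz) + (size_t)nz * (reflect_idx(y, ny) +
           (size_t)ny * reflect_idx(x, nx))];
  };

  const double ia2 = 1.0 / (2.0 * alpha * alpha);
  const double ib2 = 1.0 / (2.0 * beta * beta);
  double maxS2 = 0.0;
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  for (int si = 0; si < ns; ++si) {
    double s = scales[si];
    P[si].assign(n, 0.f);
    S2s[si].assign(n, 0.f);
    for (size_t i = 0; i < n; ++i) g[i] = (float)vol[i];
    conv_axis(g, nz, ny, nx, gauss_kernel(s / dz), 0);
    conv_axis(g, nz, ny, nx, gauss_kernel(s / dy), 1);
    conv_axis(g, nz, ny, nx, gauss_kernel(s / dx), 2);
    const double s2 = s * s; // gamma-normalization of second derivatives
    const double izz = s2 / (dz * dz), iyy = s2 / (dy * dy),
                 ixx = s2 / (dx * dx), izy = s2 * 0.25 / (dz * dy),
                 izx = s2 * 0.25 / (dz * dx), iyx = s2 * 0.25 / (dy * dx);
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        for (int z = 0; z < nz; ++z) {
          double c0 = at(g, z, y, x);
          double hzz = izz * (at(g, z + 1, y, x) - 2 * c0 + at(g, z - 1, y, x));
          double hyy = iyy * (at(g, z, y + 1, x) - 2 * c0 + at(g, z, y - 1, x));
          double hxx = ixx * (at(g, z, y, x + 1) - 2 * c0 + at(g, z, y, x - 1));
          double hzy = izy * (at(g, z + 1, y + 1, x) - at(g, z + 1, y - 1, x) -
                              at(g, z - 1, y + 1, x) + at(g, z - 1, y - 1, x));
          double hzx = izx * (at(g, z + 1, y, x + 1) - at(g, z + 1, y, x - 1) -
                              at(g, z - 1, y, x + 1) + at(g, z - 1, y, x - 1));
          double hyx = iyx * (at(g, z, y + 1, x + 1) - at(g, z, y + 1, x - 1) -
                              at(g, z, y - 1, x + 1) + at(g, z, y - 1, x - 1));
          double e1, e2, e3;
          eig3(hzz, hzy, hzx, hyy, hyx, hxx, e1, e2, e3);
          size_t idx = z + (size_t)nz * (y + (size_t)ny * x);
          bool ok = bright ? (e2 < 0 && e3 < 0) : (e2 > 0 && e3 > 0);
          if (!ok) continue;
          double Ra = std::fabs(e2) / std::fabs(e3);
          double Rb = std::fabs(e1) / std::sqrt(std::fabs(e2 * e3));
          double S2 = e1 * e1 + e2 * e2 + e3 * e3;
          P[si][idx] = (float)((1.0 - std::exp(-Ra * Ra * ia2)) *
                               std::exp(-Rb * Rb * ib2));
          S2s[si][idx] = (float)S2;
          if (S2 > maxS2) maxS2 = S2;
        }
      }
    }
  }
  double c = (cpar > 0) ? cpar : 0.5 * std::sqrt(maxS2);
  if (c <= 0) c = 1e-10;
  const double ic2 = 1.0 / (2.0 * c * c);
  for (int si = 0; si < ns; ++si) {
    for (size_t i = 0; i < n; ++i) {
      if (P[si][i] == 0.f) continue;
      double v = (double)P[si][i] * (1.0 - std::exp(-(double)S2s[si][i] * ic2));
      if (v > out[i]) out[i] = v;
    }
  }
  return out;
}
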