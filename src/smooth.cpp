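#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

int reflect_idx(int i, int n);

static std::vector<float> gk(double sigma) {
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

void conv_axis_pub(std::vector<float> &v, int nz, int ny, int nx,
                   const std::vector<float> &ker, int axis);

// Separable Gaussian smoothing with per-axis sigmas in voxels (sigma <= 0
// skips the axis). Used for point-spread-function emulation in phantoms.
// [[Rcpp::export]]
NumericVector gauss_smooth_cpp(NumericVector vol, IntegerVector dims,
                               NumericVector sigma_vox) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const size_t n = (size_t)nz * ny * nx;
  std::vector<float> g(n);
  for (size_t i = 0; i < n; ++i) g[i] = (float)vol[i];
  for (int axis = 0; axis < 3; ++axis)
    if (sigma_vox[axis] > 0)
      conv_axis_pub(g, nz, ny, nx, gk(sigma_vox[axis]), axis);
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = g[i];
  return out;
}
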