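#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Mark all voxels within radius_mm (anisotropic physical distance) of the
// polyline path_mm (n x 3, columns z,y,x in mm) in the integer buffer `buf`
// (modified in place; dim = c(nz, ny, nx)). Voxel centers sit at
// (index + 0.5) * spacing, 0-based. Errors if the path leaves the volume.
// [[Rcpp::export]]
void stamp_tube_cpp(IntegerVector buf, IntegerVector dims,
                    NumericVector spacing, NumericMatrix path_mm,
                    double radius_mm) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  const double ez = nz * dz, ey = ny * dy, ex = nx * dx;
  const int np = path_mm.nrow();
  for (int i = 0; i < np; ++i) {
    if (path_mm(i, 0) < 0 || path_mm(i, 0) > ez || path_mm(i, 1) < 0 ||
        path_mm(i, 1) > ey || path_mm(i, 2) < 0 || path_mm(i, 2) > ex)
      stop("path exits volume at point %d (z=%.4f, y=%.4f, x=%.4f mm)", i + 1,
           path_mm(i, 0), path_mm(i, 1), path_mm(i, 2));
  }
  double step = 0.45 * std::min(dz, std::min(dy, dx));
  auto stamp = [&](double pz, double py, double px) {
    int z0 = std::max(0, (int)std::floor((pz - radius_mm) / dz - 0.5));
    int z1 = std::min(nz - 1, (int)std::ceil((pz + radius_mm) / dz));
    int y0 = std::max(0, (int)std::floor((py - radius_mm) / dy - 0.5));
    int y1 = std::min(ny - 1, (int)std::ceil((py + radius_mm) / dy));
    int x0 = std::max(0, (int)std::floor((px - radius_mm) / dx - 0.5));
    int x1 = std::min(nx - 1, (int)std::ceil((px + radius_mm) / dx));
    const double r2 = radius_mm * radius_mm;
    for (int x = x0; x <= x1; ++x) {
      double ddx = (x + 0.5) * dx - px;
      for (int y = y0; y <= y1; ++y) {
        double ddy = (y + 0.5) * dy - py;
        for (int z = z0; z <= z1; ++z) {
          double ddz = (z + 0.5) * dz - pz;
          if (ddz * ddz + ddy * ddy + ddx * ddx <= r2)
            buf[z + (size_t)nz * (y + (size_t)ny * x)] = 1;
        }
      }
    }
  };
  for (int i = 0; i + 1 < np; ++i) {
    double az = path_mm(i, 0), ay = path_mm(i, 1), ax = path_mm(i, 2);
    double bz = path_mm(i + 1, 0), by = path_mm(i + 1, 1), bx = path_mm(i + 1, 2);
    double len = std::sqrt((bz - az) * (bz - az) + (by - ay) * (by - ay) +
                           (bx - ax) * (bx - ax));
    int nstep = std::max(1, (int)std::ceil(len / step));
    for (int s = 0; s <= nstep; ++s) {
      double t = (double)s / nstep;
      stamp(az + t * (bz - az), ay + t * (by - ay), ax + t * (bx - ax));
    }
  }
  if (np == 1) stamp(path_mm(0, 0), path_mm(0, 1), path_mm(0, 2));
}
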