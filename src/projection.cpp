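#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parallel-beam forward projector, rotation about the z axis.
// vol: numeric array with dim (nx, ny, nz); voxel centres at integer offsets,
// rotation centre at ((nx-1)/2, (ny-1)/2). Rays travel in the x-y plane;
// detector column s is the coordinate along u = (cos t, sin t). Output has
// dim (nx, nz, n_angles): line integrals in units of (value * voxel_size),
// with voxel_size applied by the caller (step here is in voxel units).
// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector vol, IntegerVector dim,
                                  NumericVector angles_rad, double t_step) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int na = angles_rad.size();
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  const double half_diag = 0.5 * std::sqrt((double)nx * nx + (double)ny * ny);
  const int nt = (int)std::ceil(2.0 * half_diag / t_step) + 1;

  NumericVector out(Dimension(nx, nz, na));
  const double *v = vol.begin();
  double *o = out.begin();

  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles_rad[a]), st = std::sin(angles_rad[a]);
    for (int s = 0; s < nx; ++s) {
      const double sc = s - cx;  // detector coordinate in voxel units
      for (int it = 0; it < nt; ++it) {
        const double t = -half_diag + it * t_step;
        const double x = cx + sc * ct - t * st;
        const double y = cy + sc * st + t * ct;
        if (x < 0 || x > nx - 1 || y < 0 || y > ny - 1) continue;
        const int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
        const int x1 = (x0 < nx - 1) ? x0 + 1 : x0;
        const int y1 = (y0 < ny - 1) ? y0 + 1 : y0;
        const double fx = x - x0, fy = y - y0;
        const double w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy);
        const double w01 = (1 - fx) * fy, w11 = fx * fy;
        const size_t b00 = (size_t)x0 + (size_t)nx * y0;
        const size_t b10 = (size_t)x1 + (size_t)nx * y0;
        const size_t b01 = (size_t)x0 + (size_t)nx * y1;
        const size_t b11 = (size_t)x1 + (size_t)nx * y1;
        const size_t plane = (size_t)nx * ny;
        for (int k = 0; k < nz; ++k) {
          const size_t off = plane * k;
          const double val = w00 * v[b00 + off] + w10 * v[b10 + off] +
                             w01 * v[b01 + off] + w11 * v[b11 + off];
          o[(size_t)s + (size_t)nx * k + (size_t)nx * nz * a] += val * t_step;
        }
      }
    }
  }
  return out;
}

// Backprojection of one filtered sinogram (n_angles x n_det) onto a
// grid_n x grid_n slice. Detector sampling step equals the grid pixel, so
// coordinates stay in pixel units; the caller applies pi/n_angles and any
// physical scaling.
// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix filtered, NumericVector angles_rad,
                              int grid_n) {
  const int na = filtered.nrow(), nd = filtered.ncol();
  const double cg = 0.5 * (grid_n - 1), cd = 0.5 * (nd - 1);
  NumericMatrix out(grid_n, grid_n);

  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles_rad[a]), st = std::sin(angles_rad[a]);
    for (int j = 0; j < grid_n; ++j) {      // y index (second dim)
      const double y = j - cg;
      for (int i = 0; i < grid_n; ++i) {    // x index (first dim)
        const double x = i - cg;
        const double s = x * ct + y * st + cd;
        if (s < 0 || s > nd - 1) continue;
        const int s0 = (int)std::floor(s);
        const int s1 = (s0 < nd - 1) ? s0 + 1 : s0;
        const double f = s - s0;
        out(i, j) += (1 - f) * filtered(a, s0) + f * filtered(a, s1);
      }
    }
  }
  return out;
}
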