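#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Separable 3D Gaussian smoothing, reflecting boundaries.
// vol has dim (nx, ny, nz); sigma in voxel units (may differ per axis? no —
// isotropic sigma, as detection scales are isotropic in physical units on an
// isotropic grid).
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector vol, IntegerVector dim, double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz;
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * r + 1);
  double ksum = 0.0;
  for (int i = -r; i <= r; ++i) {
    kern[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    ksum += kern[i + r];
  }
  for (double &k : kern) k /= ksum;

  NumericVector out(n);
  std::vector<double> tmp(n);
  const double *src = vol.begin();
  double *a = out.begin();
  double *b = tmp.data();

  // reflect index into [0, m-1]
  auto refl = [](int i, int m) {
    if (m == 1) return 0;
    while (i < 0 || i >= m) { if (i < 0) i = -i - 1; if (i >= m) i = 2 * m - i - 1; }
    return i;
  };

  const size_t sx = 1, sy = (size_t)nx, sz = (size_t)nx * ny;
  // pass along x: src -> a
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const size_t base = sy * j + sz * k;
      for (int i = 0; i < nx; ++i) {
        double acc = 0;
        for (int d = -r; d <= r; ++d) acc += kern[d + r] * src[base + sx * refl(i + d, nx)];
        a[base + sx * i] = acc;
      }
    }
  // pass along y: a -> b
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      const size_t base = sx * i + sz * k;
      for (int j = 0; j < ny; ++j) {
        double acc = 0;
        for (int d = -r; d <= r; ++d) acc += kern[d + r] * a[base + sy * refl(j + d, ny)];
        b[base + sy * j] = acc;
      }
    }
  // pass along z: b -> a
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      const size_t base = sx * i + sy * j;
      for (int k = 0; k < nz; ++k) {
        double acc = 0;
        for (int d = -r; d <= r; ++d) acc += kern[d + r] * b[base + sz * refl(k + d, nz)];
        a[base + sz * k] = acc;
      }
    }
  out.attr("dim") = dim;
  return out;
}

static inline void eig3_sym(double a11, double a22, double a33,
                            double a12, double a13, double a23,
                            double ev[3]) {
  // closed-form eigenvalues of a symmetric 3x3 matrix (trigonometric method)
  const double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  if (p1 < 1e-30) { ev[0] = a11; ev[1] = a22; ev[2] = a33; return; }
  const double q = (a11 + a22 + a33) / 3.0;
  const double p2 = (a11 - q) * (a11 - q) + (a22 - q) * (a22 - q) +
                    (a33 - q) * (a33 - q) + 2.0 * p1;
  const double p = std::sqrt(p2 / 6.0);
  const double b11 = (a11 - q) / p, b22 = (a22 - q) / p, b33 = (a33 - q) / p;
  const double b12 = a12 / p, b13 = a13 / p, b23 = a23 / p;
  double detB = b11 * (b22 * b33 - b23 * b23) - b12 * (b12 * b33 - b23 * b13) +
                b13 * (b12 * b23 - b22 * b13);
  double r = detB / 2.0;
  if (r < -1.0) r = -1.0; else if (r > 1.0) r = 1.0;
  const double phi = std::acos(r) / 3.0;
  ev[0] = q + 2.0 * p * std::cos(phi);
  ev[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
  ev[1] = 3.0 * q - ev[0] - ev[2];
}

// Frangi-type tubularity of a pre-smoothed volume (bright tubes on dark
// background). Second derivatives by central differences, scale-normalized
// by sigma^2. Returns list(strength, axis): axis codes 0/1/2 give the grid
// axis most aligned with the local ridge direction (eigenvector of the
// smallest-|lambda| eigenvalue), used for transverse local-maximum tests.
// [[Rcpp::export]]
List cpp_vesselness(NumericVector smoothed, IntegerVector dim, double sigma,
                    double alpha, double beta, double c_norm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz;
  const size_t sx = 1, sy = (size_t)nx, sz = (size_t)nx * ny;
  const double *v = smoothed.begin();
  NumericVector strength(n);
  IntegerVector axis(n);
  std::vector<double> l1(n), l2(n), l3(n);
  std::vector<signed char> ax(n);
  const double s2 = sigma * sigma;

  auto idx = [&](int i, int j, int k) { return sx * i + sy * j + sz * k; };
  auto clampi = [](int i, int m) { return i < 0 ? 0 : (i >= m ? m - 1 : i); };

  double smax2 = 0.0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int im = clampi(i - 1, nx), ip = clampi(i + 1, nx);
        const int jm = clampi(j - 1, ny), jp = clampi(j + 1, ny);
        const int km = clampi(k - 1, nz), kp = clampi(k + 1, nz);
        const double c = v[idx(i, j, k)];
        const double hxx = v[idx(ip, j, k)] - 2 * c + v[idx(im, j, k)];
        const double hyy = v[idx(i, jp, k)] - 2 * c + v[idx(i, jm, k)];
        const double hzz = v[idx(i, j, kp)] - 2 * c + v[idx(i, j, km)];
        const double hxy = 0.25 * (v[idx(ip, jp, k)] - v[idx(im, jp, k)] -
                                   v[idx(ip, jm, k)] + v[idx(im, jm, k)]);
        const double hxz = 0.25 * (v[idx(ip, j, kp)] - v[idx(im, j, kp)] -
                                   v[idx(ip, j, km)] + v[idx(im, j, km)]);
        const double hyz = 0.25 * (v[idx(i, jp, kp)] - v[idx(i, jm, kp)] -
                                   v[idx(i, jp, km)] + v[idx(i, jm, km)]);
        double ev[3];
        eig3_sym(s2 * hxx, s2 * hyy, s2 * hzz, s2 * hxy, s2 * hxz, s2 * hyz, ev);
        // sort by |lambda|: e1 smallest
        double e[3] = {ev[0], ev[1], ev[2]};
        for (int p = 0; p < 2; ++p)
          for (int q = 0; q < 2 - p; ++q)
            if (std::fabs(e[q]) > std::fabs(e[q + 1])) std::swap(e[q], e[q + 1]);
        const size_t id = idx(i, j, k);
        l1[id] = e[0]; l2[id] = e[1]; l3[id] = e[2];
        const double ss = e[0] * e[0] + e[1] * e[1] + e[2] * e[2];
        if (ss > smax2) smax2 = ss;

        // ridge axis: eigenvector for e[0] via cross products of (H - e0 I)
        // rows; all three row pairs are tried and the numerically largest
        // product kept, which is scale-invariant (no absolute threshold)
        const double a = s2 * hxx - e[0], b = s2 * hyy - e[0],
                     cc = s2 * hzz - e[0];
        const double dd = s2 * hxy, ee = s2 * hxz, ff = s2 * hyz;
        const double cx[3] = {dd * ff - ee * b, dd * cc - ee * ff,
                              b * cc - ff * ff};
        const double cy[3] = {ee * dd - a * ff, ee * ee - a * cc,
                              ff * ee - dd * cc};
        const double cz[3] = {a * b - dd * dd, a * ff - dd * ee,
                              dd * ff - b * ee};
        int bestp = 0;
        double bestn = -1.0;
        for (int p = 0; p < 3; ++p) {
          const double n2 = cx[p] * cx[p] + cy[p] * cy[p] + cz[p] * cz[p];
          if (n2 > bestn) { bestn = n2; bestp = p; }
        }
        const double axv = std::fabs(cx[bestp]), ayv = std::fabs(cy[bestp]),
                     azv = std::fabs(cz[bestp]);
        ax[id] = (axv >= ayv && axv >= azv) ? 0 : (ayv >= azv ? 1 : 2);
      }

  // structureness constant: fixed (volume-contrast based) when supplied, so
  // responses stay comparable across scales; else half the max Frobenius norm
  const double c2 = c_norm > 0 ? c_norm * c_norm : std::max(0.25 * smax2, 1e-30);
  const double a2 = 2.0 * alpha * alpha, b2 = 2.0 * beta * beta;
  for (size_t id = 0; id < n; ++id) {
    const double e2 = l2[id], e3 = l3[id];
    if (e2 >= 0 || e3 >= 0) { strength[id] = 0; axis[id] = ax[id]; continue; }
    const double ra = std::fabs(e2) / std::fabs(e3);
    const double rb = std::fabs(l1[id]) / std::sqrt(std::fabs(e2 * e3));
    const double ss = l1[id] * l1[id] + e2 * e2 + e3 * e3;
    strength[id] = (1.0 - std::exp(-ra * ra / a2)) *
                   std::exp(-rb * rb / b2) *
                   (1.0 - std::exp(-ss / (2.0 * c2)));
    axis[id] = ax[id];
  }
  strength.attr("dim") = dim;
  axis.attr("dim") = dim;
  return List::create(_["strength"] = strength, _["axis"] = axis);
}

// Candidate ridge points: voxels above `thresh` that are strict maxima of
// `strength` within the 3x3 plane transverse to their ridge axis.
// Returns 1-based voxel indices (i, j, k) as an integer matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_transverse_maxima(NumericVector strength, IntegerVector axis,
                                    IntegerVector dim, double thresh) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t sx = 1, sy = (size_t)nx, sz = (size_t)nx * ny;
  const double *s = strength.begin();
  const int *a = axis.begin();
  std::vector<int> out;

  for (int k = 1; k < nz - 1; ++k)
    for (int j = 1; j < ny - 1; ++j)
      for (int i = 1; i < nx - 1; ++i) {
        const size_t id = sx * i + sy * j + sz * k;
        const double c = s[id];
        if (c <= thresh) continue;
        const int axc = a[id];
        bool ismax = true;
        for (int dk = -1; dk <= 1 && ismax; ++dk)
          for (int dj = -1; dj <= 1 && ismax; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              if (axc == 0 && (dj == 0 && dk == 0)) continue;  // skip along-axis
              if (axc == 1 && (di == 0 && dk == 0)) continue;
              if (axc == 2 && (di == 0 && dj == 0)) continue;
              if (axc == 0 && di != 0) continue;               // stay in plane
              if (axc == 1 && dj != 0) continue;
              if (axc == 2 && dk != 0) continue;
              if (s[id + (long)di * sx + (long)dj * sy + (long)dk * sz] >= c) {
                ismax = false; break;
              }
            }
        if (ismax) { out.push_back(i + 1); out.push_back(j + 1); out.push_back(k + 1); }
      }

  const int m = out.size() / 3;
  IntegerMatrix res(m, 3);
  for (int r = 0; r < m; ++r) {
    res(r, 0) = out[3 * r]; res(r, 1) = out[3 * r + 1]; res(r, 2) = out[3 * r + 2];
  }
  return res;
}
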