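#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1D squared-distance transform (Felzenszwalb & Huttenlocher)
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Euclidean distance (in voxel units) from each foreground voxel to the
// nearest background voxel. mask: logical/integer array dim (nx, ny, nz).
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz;
  const size_t sx = 1, sy = (size_t)nx, sz = (size_t)nx * ny;
  const double INF = 1e18;
  std::vector<double> g(n);
  for (size_t i = 0; i < n; ++i) g[i] = mask[i] ? INF : 0.0;

  std::vector<double> f(std::max(nx, std::max(ny, nz)));
  std::vector<double> d(f.size());
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const size_t base = sy * j + sz * k;
      for (int i = 0; i < nx; ++i) f[i] = g[base + sx * i];
      dt1d(f, d, nx);
      for (int i = 0; i < nx; ++i) g[base + sx * i] = d[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      const size_t base = sx * i + sz * k;
      for (int j = 0; j < ny; ++j) f[j] = g[base + sy * j];
      dt1d(f, d, ny);
      for (int j = 0; j < ny; ++j) g[base + sy * j] = d[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      const size_t base = sx * i + sy * j;
      for (int k = 0; k < nz; ++k) f[k] = g[base + sz * k];
      dt1d(f, d, nz);
      for (int k = 0; k < nz; ++k) g[base + sz * k] = d[k];
    }

  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  out.attr("dim") = dim;
  return out;
}

// 26-connected component labelling; labels 1..n_components, 0 = background.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<size_t> stack;
  int next = 0;

  for (size_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || lab[seed] != 0) continue;
    ++next;
    lab[seed] = next;
    stack.push_back(seed);
    while (!stack.empty()) {
      const size_t cur = stack.back();
      stack.pop_back();
      const int i = cur % nx, j = (cur / nx) % ny, k = cur / ((size_t)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            const int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
              continue;
            const size_t nb = (size_t)ii + (size_t)nx * jj + (size_t)nx * ny * kk;
            if (mask[nb] && lab[nb] == 0) { lab[nb] = next; stack.push_back(nb); }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// ---- topology-preserving 3D thinning -------------------------------------

// neighbourhood offsets are indexed as 3x3x3 cube positions 0..26,
// pos = (di+1) + 3*(dj+1) + 9*(dk+1); centre = 13.
static inline int cube_pos(int di, int dj, int dk) {
  return (di + 1) + 3 * (dj + 1) + 9 * (dk + 1);
}

// number of 26-connected components of foreground within N26 (centre removed)
static int n26_components(const bool fg[27]) {
  bool seen[27] = {false};
  int comps = 0;
  for (int p = 0; p < 27; ++p) {
    if (p == 13 || !fg[p] || seen[p]) continue;
    ++comps;
    std::vector<int> st{p};
    seen[p] = true;
    while (!st.empty()) {
      const int c = st.back();
      st.pop_back();
      const int ci = c % 3 - 1, cj = (c / 3) % 3 - 1, ck = c / 9 - 1;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            const int ni = ci + di, nj = cj + dj, nk = ck + dk;
            if (ni < -1 || ni > 1 || nj < -1 || nj > 1 || nk < -1 || nk > 1)
              continue;
            const int q = cube_pos(ni, nj, nk);
            if (q == 13 || q == c || !fg[q] || seen[q]) continue;
            seen[q] = true;
            st.push_back(q);
          }
    }
  }
  return comps;
}

// number of 6-connected components of background within N18 that touch the
// centre by a 6-neighbour (Malandain-Bertrand background condition)
static int n6_bg_components(const bool fg[27]) {
  // N18: positions with at most two non-zero offsets
  bool in18[27];
  for (int p = 0; p < 27; ++p) {
    const int di = p % 3 - 1, dj = (p / 3) % 3 - 1, dk = p / 9 - 1;
    in18[p] = (std::abs(di) + std::abs(dj) + std::abs(dk) <= 2) && p != 13;
  }
  const int six[6] = {cube_pos(-1, 0, 0), cube_pos(1, 0, 0), cube_pos(0, -1, 0),
                      cube_pos(0, 1, 0),  cube_pos(0, 0, -1), cube_pos(0, 0, 1)};
  bool seen[27] = {false};
  int comps = 0;
  for (int s = 0; s < 6; ++s) {
    const int p = six[s];
    if (fg[p] || seen[p]) continue;
    ++comps;
    std::vector<int> st{p};
    seen[p] = true;
    while (!st.empty()) {
      const int c = st.back();
      st.pop_back();
      const int ci = c % 3 - 1, cj = (c / 3) % 3 - 1, ck = c / 9 - 1;
      const int moves[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
      for (int m = 0; m < 6; ++m) {
        const int ni = ci + moves[m][0], nj = cj + moves[m][1], nk = ck + moves[m][2];
        if (ni < -1 || ni > 1 || nj < -1 || nj > 1 || nk < -1 || nk > 1) continue;
        const int q = cube_pos(ni, nj, nk);
        if (q == 13 || !in18[q] || fg[q] || seen[q]) continue;
        seen[q] = true;
        st.push_back(q);
      }
    }
  }
  return comps;
}

// Medial-axis thinning: iteratively delete simple, non-endpoint border voxels
// in six directional subiterations until stable. Preserves 26-connectivity of
// the foreground and 6-connectivity of the background; endpoints (voxels with
// <= 1 foreground 26-neighbour) are kept so curve skeletons survive.
// [[Rcpp::export]]
LogicalVector cpp_skeletonize3d(LogicalVector mask, IntegerVector dim,
                                int max_sweeps = -1) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz;
  std::vector<char> m(n);
  for (size_t i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;

  auto at = [&](int i, int j, int k) -> char {
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) return 0;
    return m[(size_t)i + (size_t)nx * j + (size_t)nx * ny * k];
  };

  const int dirs[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};
  std::vector<size_t> cand;
  bool changed = true;
  int sweep = 0;
  while (changed && (max_sweeps < 0 || sweep++ < max_sweeps)) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      // phase 1: collect voxels that are border in direction d NOW, so each
      // subiteration peels at most one layer (deletions during phase 2 must
      // not expose new candidates within the same sweep)
      cand.clear();
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            const size_t id = (size_t)i + (size_t)nx * j + (size_t)nx * ny * k;
            if (!m[id]) continue;
            if (at(i + dirs[d][0], j + dirs[d][1], k + dirs[d][2])) continue;
            cand.push_back(id);
          }
      // phase 2: sequential deletion with the simple-point test re-evaluated
      // against the current mask, which keeps topology exact
      for (size_t c = 0; c < cand.size(); ++c) {
        const size_t id = cand[c];
        if (!m[id]) continue;
        const int i = id % nx, j = (id / nx) % ny, k = id / ((size_t)nx * ny);
        bool fg[27];
        int nnb = 0, nb1 = -1, nb2 = -1;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              const int p = cube_pos(di, dj, dk);
              fg[p] = at(i + di, j + dj, k + dk) != 0;
              if (p != 13 && fg[p]) { ++nnb; if (nb1 < 0) nb1 = p; else nb2 = p; }
            }
        if (nnb <= 1) continue;  // endpoint: keep
        if (nnb == 2) {
          // "thick endpoint": both neighbours mutually 26-adjacent means the
          // voxel caps a (possibly diagonal) line end; deleting such caps in
          // sequence lets a whole branch retract within one sweep, so they
          // are protected like plain endpoints
          const int i1 = nb1 % 3, j1 = (nb1 / 3) % 3, k1 = nb1 / 9;
          const int i2 = nb2 % 3, j2 = (nb2 / 3) % 3, k2 = nb2 / 9;
          if (std::abs(i1 - i2) <= 1 && std::abs(j1 - j2) <= 1 &&
              std::abs(k1 - k2) <= 1)
            continue;
        }
        if (n26_components(fg) != 1) continue;
        if (n6_bg_components(fg) != 1) continue;
        m[id] = 0;
        changed = true;
      }
    }
  }

  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = m[i] != 0;
  out.attr("dim") = dim;
  return out;
}
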