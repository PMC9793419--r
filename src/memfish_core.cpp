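#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// 1D squared Euclidean distance transform (Felzenszwalb & Huttenlocher 2012),
// lower envelope of parabolas, with physical sample spacing s.
// f: input squared distances at grid positions i*s; d: output.
// ---------------------------------------------------------------------------
static void dt1d(const double *f, double *d, int n, double s,
                 int *v, double *z) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    while (true) {
      double xv = v[k] * s;
      double sep = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (sep <= z[k]) {
        --k;
      } else {
        ++k;
        v[k] = q;
        z[k] = sep;
        z[k + 1] = INF;
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * s;
    d[q] = dx * dx + f[v[k]];
  }
}

// Anisotropic Euclidean distance transform of a 3D logical mask.
// Returns, for every voxel, the distance (same units as spacing) to the
// nearest FALSE voxel centre. dim = (nz, ny, nx); array is column-major in z.
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const double BIG = 1e30;
  NumericVector out(n);
  // squared distances, init 0 on background, BIG on foreground
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? BIG : 0.0;

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along z (stride 1)
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      for (int q = 0; q < nz; ++q) f[q] = out[base + q];
      dt1d(f.data(), d.data(), nz, spacing[0], v.data(), z.data());
      for (int q = 0; q < nz; ++q) out[base + q] = d[q];
    }
  // pass along y (stride nz)
  for (int x = 0; x < nx; ++x)
    for (int zz = 0; zz < nz; ++zz) {
      R_xlen_t base = zz + (R_xlen_t)nz * ny * x;
      for (int q = 0; q < ny; ++q) f[q] = out[base + (R_xlen_t)nz * q];
      dt1d(f.data(), d.data(), ny, spacing[1], v.data(), z.data());
      for (int q = 0; q < ny; ++q) out[base + (R_xlen_t)nz * q] = d[q];
    }
  // pass along x (stride nz*ny)
  const R_xlen_t sx = (R_xlen_t)nz * ny;
  for (int y = 0; y < ny; ++y)
    for (int zz = 0; zz < nz; ++zz) {
      R_xlen_t base = zz + (R_xlen_t)nz * y;
      for (int q = 0; q < nx; ++q) f[q] = out[base + sx * q];
      dt1d(f.data(), d.data(), nx, spacing[2], v.data(), z.data());
      for (int q = 0; q < nx; ++q) out[base + sx * q] = d[q];
    }

  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian convolution with reflecting boundaries.
// sigma is given in voxels per axis (z, y, x); kernels normalised to sum 1,
// so constants are preserved exactly.
// ---------------------------------------------------------------------------
static std::vector<double> gauss_kernel(double sigma) {
  if (sigma <= 0) return std::vector<double>(1, 1.0);
  int r = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &kv : k) kv /= s;
  return k;
}

static inline int reflect(int i, int n) {
  // reflect-101-free simple reflection: ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

static void conv_axis(std::vector<double> &a, int nz, int ny, int nx,
                      int axis, const std::vector<double> &k) {
  int r = ((int)k.size() - 1) / 2;
  if (r == 0) return;
  int nax = axis == 0 ? nz : (axis == 1 ? ny : nx);
  R_xlen_t stride = axis == 0 ? 1 : (axis == 1 ? (R_xlen_t)nz : (R_xlen_t)nz * ny);
  std::vector<double> line(nax), res(nax);
  int n1 = axis == 0 ? ny : nz;
  int n2 = axis == 2 ? ny : nx;
  for (int j2 = 0; j2 < n2; ++j2)
    for (int j1 = 0; j1 < n1; ++j1) {
      R_xlen_t base;
      if (axis == 0)      base = (R_xlen_t)nz * (j1 + (R_xlen_t)ny * j2);
      else if (axis == 1) base = j1 + (R_xlen_t)nz * ny * j2;
      else                base = j1 + (R_xlen_t)nz * j2;
      for (int q = 0; q < nax; ++q) line[q] = a[base + stride * q];
      for (int q = 0; q < nax; ++q) {
        double s = 0.0;
        for (int t = -r; t <= r; ++t) s += k[t + r] * line[reflect(q + t, nax)];
        res[q] = s;
      }
      for (int q = 0; q < nax; ++q) a[base + stride * q] = res[q];
    }
}

// [[Rcpp::export(name = ".gauss3d")]]
NumericVector gauss3d(NumericVector vol, IntegerVector dim, NumericVector sigma_vox) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<double> a(vol.begin(), vol.end());
  conv_axis(a, nz, ny, nx, 0, gauss_kernel(sigma_vox[0]));
  conv_axis(a, nz, ny, nx, 1, gauss_kernel(sigma_vox[1]));
  conv_axis(a, nz, ny, nx, 2, gauss_kernel(sigma_vox[2]));
  NumericVector out(n);
  std::copy(a.begin(), a.end(), out.begin());
  return out;
}

// ---------------------------------------------------------------------------
// 26-connected local maxima above a threshold. Border (1-voxel margin)
// excluded. Plateau voxels (>= all neighbours) are all reported; the caller
// deduplicates deterministically via the minimum-separation rule.
// Returns 1-based linear indices.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".local_max26")]]
IntegerVector local_max26(NumericVector vol, IntegerVector dim, double threshold) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<R_xlen_t> hits;
  const R_xlen_t sy = nz, sx = (R_xlen_t)nz * ny;
  for (int x = 1; x < nx - 1; ++x)
    for (int y = 1; y < ny - 1; ++y)
      for (int z = 1; z < nz - 1; ++z) {
        R_xlen_t i = z + sy * y + sx * x;
        double v = vol[i];
        if (v <= threshold) continue;
        bool ismax = true;
        for (int dx = -1; dx <= 1 && ismax; ++dx)
          for (int dy = -1; dy <= 1 && ismax; ++dy)
            for (int dz = -1; dz <= 1; ++dz) {
              if (!dx && !dy && !dz) continue;
              if (vol[i + dz + sy * dy + sx * dx] > v) { ismax = false; break; }
            }
        if (ismax) hits.push_back(i + 1);
      }
  return IntegerVector(hits.begin(), hits.end());
}

// ---------------------------------------------------------------------------
// Connected-component labelling of a 3D logical mask (6- or 26-connectivity),
// iterative flood fill. Returns integer labels (0 = background).
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".label3d")]]
IntegerVector label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  const R_xlen_t sy = nz, sx = (R_xlen_t)nz * ny;
  std::vector<std::array<int, 3>> nbr;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (!dx && !dy && !dz) continue;
        int ad = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && ad != 1) continue;
        nbr.push_back({dz, dy, dx});
      }
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++cur;
    stack.push_back(i);
    lab[i] = cur;
    while (!stack.empty()) {
      R_xlen_t j = stack.back();
      stack.pop_back();
      int z = (int)(j % nz);
      int y = (int)((j / nz) % ny);
      int x = (int)(j / sx);
      for (auto &d : nbr) {
        int z2 = z + d[0], y2 = y + d[1], x2 = x + d[2];
        if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx) continue;
        R_xlen_t j2 = z2 + sy * y2 + sx * x2;
        if (mask[j2] && !lab[j2]) { lab[j2] = cur; stack.push_back(j2); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
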