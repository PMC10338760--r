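#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform (lower envelope of parabolas) on a sampled
// line with sample spacing h.  f holds squared distances on entry and exit.
static void dt1d(std::vector<double>& f, double h, std::vector<int>& v,
                 std::vector<double>& z, std::vector<double>& d) {
  const int n = (int)f.size();
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;  // infinite parabolas never attain the min
    double xq = q * h;
    double s = 0.0;
    while (k >= 0) {
      double xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = (k == 0) ? -INF : s;
    z[k + 1] = INF;
  }
  if (k < 0) return;  // whole line infinite: nothing to relax
  int j = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[j + 1] < xq) ++j;
    double dx = xq - v[j] * h;
    d[q] = dx * dx + f[v[j]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Squared Euclidean distance (mm^2) from every voxel center to the nearest
// true voxel center, honouring anisotropic spacing.  Exact (Felzenszwalb &
// Huttenlocher separable transform).
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      f.assign(out.begin() + base, out.begin() + base + nx);
      dt1d(f, spacing[0], v, z, d);
      for (int i = 0; i < nx; ++i) out[base + i] = f[i];
    }
  // along y
  f.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)nx * j];
      dt1d(f, spacing[1], v, z, d);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nx * j] = f[j];
    }
  // along z
  f.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      R_xlen_t stride = (R_xlen_t)nx * ny;
      for (int k = 0; k < nz; ++k) f[k] = out[base + stride * k];
      dt1d(f, spacing[2], v, z, d);
      for (int k = 0; k < nz; ++k) out[base + stride * k] = f[k];
    }
  return out;
}

// Connected-component labelling of a 3D logical array under 6- or
// 26-connectivity.  Labels are 1..n_components, background 0.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);

  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }

  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i = (int)(cur % nx);
      int j = (int)((cur / nx) % ny);
      int k = (int)(cur / ((R_xlen_t)nx * ny));
      for (size_t q = 0; q < dxs.size(); ++q) {
        int ii = i + dxs[q], jj = j + dys[q], kk = k + dzs[q];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t nb = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[nb] && lab[nb] == 0) {
          lab[nb] = next;
          stack.push_back(nb);
        }
      }
    }
  }
  return lab;
}

// Surface voxels: mask voxels with at least one face-adjacent neighbor that
// is outside the mask (the volume boundary counts as outside).
// [[Rcpp::export]]
LogicalVector cpp_surface_mask(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t s = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (!mask[s]) continue;
        for (int q = 0; q < 6; ++q) {
          int ii = i + dx[q], jj = j + dy[q], kk = k + dz[q];
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) {
            out[s] = true; break;
          }
          R_xlen_t nb = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
          if (!mask[nb]) { out[s] = true; break; }
        }
      }
  return out;
}

// For each row (point, mm) of a, the Euclidean distance to the nearest row
// of b.  Used for directed surface distances.
// [[Rcpp::export]]
NumericVector cpp_directed_nn(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = INF;
    double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    for (int j = 0; j < nb; ++j) {
      double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
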