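#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// "no feature anywhere" sentinel: large but finite so parabola
// intersections stay well-defined (true squared distances are < 1e8 mm^2)
static const double DT_BIG = 1e20;

// Felzenszwalb & Huttenlocher 1-D squared distance transform with sample
// positions x[i] (handles anisotropic voxel spacing).
static void dt1d(const std::vector<double>& f, const std::vector<double>& x,
                 std::vector<double>& d) {
  int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + x[q] * x[q]) - (f[v[k]] + x[v[k]] * x[v[k]])) /
               (2 * x[q] - 2 * x[v[k]]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + x[q] * x[q]) - (f[v[k]] + x[v[k]] * x[v[k]])) /
          (2 * x[q] - 2 * x[v[k]]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < x[q]) k++;
    double dx = x[q] - x[v[k]];
    d[q] = dx * dx + f[v[k]];
  }
}

// Euclidean distance (mm) from every voxel to the nearest voxel where
// `feature` is non-zero.  Infinite where no feature voxel exists.
// [[Rcpp::export(name = ".cppEdt")]]
NumericVector cppEdt(IntegerVector feature, IntegerVector dim,
                     NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> D((size_t)n);
  for (R_xlen_t i = 0; i < n; i++)
    D[i] = feature[i] ? 0.0 : DT_BIG;
  // pass along x
  {
    std::vector<double> f(nx), x(nx), d(nx);
    for (int i = 0; i < nx; i++) x[i] = i * spacing[0];
    for (int k = 0; k < nz; k++)
      for (int j = 0; j < ny; j++) {
        R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int i = 0; i < nx; i++) f[i] = D[base + i];
        dt1d(f, x, d);
        for (int i = 0; i < nx; i++) D[base + i] = d[i];
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), x(ny), d(ny);
    for (int j = 0; j < ny; j++) x[j] = j * spacing[1];
    for (int k = 0; k < nz; k++)
      for (int i = 0; i < nx; i++) {
        R_xlen_t base = i + (R_xlen_t)nx * ny * (R_xlen_t)k;
        for (int j = 0; j < ny; j++) f[j] = D[base + (R_xlen_t)nx * j];
        dt1d(f, x, d);
        for (int j = 0; j < ny; j++) D[base + (R_xlen_t)nx * j] = d[j];
      }
  }
  // pass along z
  {
    std::vector<double> f(nz), x(nz), d(nz);
    for (int k = 0; k < nz; k++) x[k] = k * spacing[2];
    R_xlen_t sz = (R_xlen_t)nx * ny;
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        R_xlen_t base = i + (R_xlen_t)nx * j;
        for (int k = 0; k < nz; k++) f[k] = D[base + sz * k];
        dt1d(f, x, d);
        for (int k = 0; k < nz; k++) D[base + sz * k] = d[k];
      }
  }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++)
    out[i] = D[i] >= 1e18 ? R_PosInf : std::sqrt(D[i]);
  return out;
}

// 6-connected component labelling of a binary grid; labels 1..n assigned in
// raster order of each component's first voxel (deterministic).
// [[Rcpp::export(name = ".cppComponents")]]
IntegerVector cppComponents(IntegerVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s]) continue;
    cur++;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int i = (int)(p % nx), j = (int)((p / nx) % ny), k = (int)(p / sz);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int q = 0; q < 6; q++) {
        int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        R_xlen_t pp = ii * sx + jj * sy + kk * sz;
        if (mask[pp] && !lab[pp]) { lab[pp] = cur; stack.push_back(pp); }
      }
    }
  }
  return lab;
}
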