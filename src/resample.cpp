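#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear sample of a 3-D array at continuous 0-based index (x,y,z).
// Returns NA_REAL when the 8-neighbourhood is not fully inside the grid.
static inline double sample_linear(const double* v, const int* d,
                                   double x, double y, double z) {
  if (x < 0.0 || y < 0.0 || z < 0.0 ||
      x > d[0] - 1.0 || y > d[1] - 1.0 || z > d[2] - 1.0)
    return NA_REAL;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == d[0] - 1) x0--;
  if (y0 == d[1] - 1) y0--;
  if (z0 == d[2] - 1) z0--;
  if (d[0] == 1) x0 = 0;
  if (d[1] == 1) y0 = 0;
  if (d[2] == 1) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  int x1 = std::min(x0 + 1, d[0] - 1);
  int y1 = std::min(y0 + 1, d[1] - 1);
  int z1 = std::min(z0 + 1, d[2] - 1);
  const R_xlen_t sx = 1, sy = d[0], sz = (R_xlen_t)d[0] * d[1];
#define V(i, j, k) v[(i) * sx + (j) * sy + (k) * sz]
  double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
  double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
  double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
  double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
#undef V
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static inline double sample_nearest(const double* v, const int* d,
                                    double x, double y, double z) {
  long xi = std::lround(x), yi = std::lround(y), zi = std::lround(z);
  if (xi < 0 || yi < 0 || zi < 0 || xi >= d[0] || yi >= d[1] || zi >= d[2])
    return NA_REAL;
  return v[xi + (R_xlen_t)d[0] * (yi + (R_xlen_t)d[1] * zi)];
}

// Resample `moving` onto a grid of dimensions `outDim`; A is the 3x4 affine
// mapping 0-based output indices to 0-based continuous moving indices.
// interp: 0 = linear, 1 = nearest.  Out-of-bounds samples become NA.
// [[Rcpp::export(name = ".cppResample")]]
NumericVector cppResample(NumericVector moving, IntegerVector movDim,
                          NumericMatrix A, IntegerVector outDim, int interp) {
  const double* v = REAL(moving);
  int d[3] = {movDim[0], movDim[1], movDim[2]};
  int n0 = outDim[0], n1 = outDim[1], n2 = outDim[2];
  NumericVector out((R_xlen_t)n0 * n1 * n2);
  double a[3][4];
  for (int r = 0; r < 3; r++)
    for (int c = 0; c < 4; c++) a[r][c] = A(r, c);
  R_xlen_t p = 0;
  for (int k = 0; k < n2; k++)
    for (int j = 0; j < n1; j++)
      for (int i = 0; i < n0; i++, p++) {
        double x = a[0][0] * i + a[0][1] * j + a[0][2] * k + a[0][3];
        double y = a[1][0] * i + a[1][1] * j + a[1][2] * k + a[1][3];
        double z = a[2][0] * i + a[2][1] * j + a[2][2] * k + a[2][3];
        out[p] = interp == 0 ? sample_linear(v, d, x, y, z)
                             : sample_nearest(v, d, x, y, z);
      }
  return out;
}

// Joint histogram of fixed-grid samples against the transformed moving
// volume.  Fixed voxels are visited with the given stride; the paired
// moving value is interpolated linearly at A %*% (i,j,k,1).  Bins are
// equal-width over [fmin,fmax] x [mmin,mmax]; samples falling outside the
// moving grid are skipped.  Returns counts plus the number of visited
// fixed voxels (for overlap-fraction diagnostics).
// [[Rcpp::export(name = ".cppJointHist")]]
List cppJointHist(NumericVector fixed, IntegerVector fixDim,
                  NumericVector moving, IntegerVector movDim,
                  NumericMatrix A, int bins,
                  double fmin, double fmax, double mmin, double mmax,
                  int stride) {
  const double* fv = REAL(fixed);
  const double* mv = REAL(moving);
  int fd[3] = {fixDim[0], fixDim[1], fixDim[2]};
  int md[3] = {movDim[0], movDim[1], movDim[2]};
  double a[3][4];
  for (int r = 0; r < 3; r++)
    for (int c = 0; c < 4; c++) a[r][c] = A(r, c);
  IntegerMatrix counts(bins, bins);
  const double fw = (fmax - fmin) > 0 ? bins / (fmax - fmin) : 0.0;
  const double mw = (mmax - mmin) > 0 ? bins / (mmax - mmin) : 0.0;
  long long n = 0, visited = 0;
  for (int k = 0; k < fd[2]; k += stride)
    for (int j = 0; j < fd[1]; j += stride)
      for (int i = 0; i < fd[0]; i += stride) {
        visited++;
        double x = a[0][0] * i + a[0][1] * j + a[0][2] * k + a[0][3];
        double y = a[1][0] * i + a[1][1] * j + a[1][2] * k + a[1][3];
        double z = a[2][0] * i + a[2][1] * j + a[2][2] * k + a[2][3];
        double m = sample_linear(mv, md, x, y, z);
        if (ISNA(m)) continue;
        double f = fv[i + (R_xlen_t)fd[0] * (j + (R_xlen_t)fd[1] * k)];
        int fb = (int)((f - fmin) * fw);
        int mb = (int)((m - mmin) * mw);
        if (fb < 0) fb = 0; else if (fb >= bins) fb = bins - 1;
        if (mb < 0) mb = 0; else if (mb >= bins) mb = bins - 1;
        counts(fb, mb)++;
        n++;
      }
  return List::create(_["counts"] = counts, _["n"] = (double)n,
                      _["visited"] = (double)visited);
}
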