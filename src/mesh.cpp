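#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <map>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Marching tetrahedra on a binary grid.
//
// Grid nodes are voxel centres carrying 0/1 values; each cell of 8 nodes is
// split into six tetrahedra around the main diagonal (a decomposition that
// induces matching face diagonals in neighbouring cells, so the extracted
// iso-0.5 surface is watertight by construction and free of the ambiguous
// configurations of cube-based marching).  Iso-vertices sit at the midpoints
// of edges joining an inside (1) and outside (0) node.
// ---------------------------------------------------------------------------

// cube corner offsets, bit order (x,y,z)
static const int CX[8] = {0, 1, 0, 1, 0, 1, 0, 1};
static const int CY[8] = {0, 0, 1, 1, 0, 0, 1, 1};
static const int CZ[8] = {0, 0, 0, 0, 1, 1, 1, 1};
// six tetrahedra sharing diagonal corner0-corner7
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
  {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};

struct MeshAcc {
  std::map<uint64_t, int> vmap;          // edge key -> vertex index
  std::vector<double> vx, vy, vz;        // vertex coordinates (grid index units)
  std::vector<int> tri;                  // triangles, 0-based triples
};

// append triangle oriented so its normal points along `dir` (outward)
static void addTri(MeshAcc& m, int a, int b, int c,
                   const double dir[3]) {
  double ux = m.vx[b] - m.vx[a], uy = m.vy[b] - m.vy[a], uz = m.vz[b] - m.vz[a];
  double wx = m.vx[c] - m.vx[a], wy = m.vy[c] - m.vy[a], wz = m.vz[c] - m.vz[a];
  double nx = uy * wz - uz * wy, ny = uz * wx - ux * wz, nz = ux * wy - uy * wx;
  if (nx * dir[0] + ny * dir[1] + nz * dir[2] < 0) std::swap(b, c);
  m.tri.push_back(a); m.tri.push_back(b); m.tri.push_back(c);
}

// [[Rcpp::export(name = ".cppMarchingTets")]]
List cppMarchingTets(IntegerVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int* v = INTEGER(mask);
  // per-cell node coordinates are derived lazily; we keep global node coords
  // implicit: node id = i + nx*(j + ny*k)
  MeshAcc acc;
  // node coordinates are recovered from the linear node id on the fly
  struct CoordFn {
    int nx, ny;
    double x(uint64_t id) const { return (double)(id % nx); }
    double y(uint64_t id) const { return (double)((id / nx) % ny); }
    double z(uint64_t id) const { return (double)(id / ((uint64_t)nx * ny)); }
  } cf{nx, ny};

  // specialised edgeVertex using cf
  auto edgeVertex = [&](uint64_t na, uint64_t nb) -> int {
    if (na > nb) std::swap(na, nb);
    uint64_t key = na * 2000000011ull + nb;
    auto it = acc.vmap.find(key);
    if (it != acc.vmap.end()) return it->second;
    int id = (int)acc.vx.size();
    acc.vmap.emplace(key, id);
    acc.vx.push_back(0.5 * (cf.x(na) + cf.x(nb)));
    acc.vy.push_back(0.5 * (cf.y(na) + cf.y(nb)));
    acc.vz.push_back(0.5 * (cf.z(na) + cf.z(nb)));
    return id;
  };

  for (int k = 0; k < nz - 1; k++)
    for (int j = 0; j < ny - 1; j++)
      for (int i = 0; i < nx - 1; i++) {
        uint64_t nid[8];
        int val[8], s = 0;
        for (int c = 0; c < 8; c++) {
          nid[c] = (uint64_t)(i + CX[c]) +
                   (uint64_t)nx * ((j + CY[c]) + (uint64_t)ny * (k + CZ[c]));
          val[c] = v[nid[c]] != 0;
          s += val[c];
        }
        if (s == 0 || s == 8) continue;
        for (int t = 0; t < 6; t++) {
          uint64_t tn[4];
          int tv[4], cin = 0;
          for (int c = 0; c < 4; c++) {
            tn[c] = nid[TETS[t][c]];
            tv[c] = val[TETS[t][c]];
            cin += tv[c];
          }
          if (cin == 0 || cin == 4) continue;
          // centroids of inside and outside nodes -> outward direction
          double ci[3] = {0, 0, 0}, co[3] = {0, 0, 0};
          int niN = 0, noN = 0;
          for (int c = 0; c < 4; c++) {
            double p[3] = {cf.x(tn[c]), cf.y(tn[c]), cf.z(tn[c])};
            if (tv[c]) { ci[0]+=p[0]; ci[1]+=p[1]; ci[2]+=p[2]; niN++; }
            else       { co[0]+=p[0]; co[1]+=p[1]; co[2]+=p[2]; noN++; }
          }
          double dir[3] = {co[0]/noN - ci[0]/niN, co[1]/noN - ci[1]/niN,
                           co[2]/noN - ci[2]/niN};
          if (cin == 1 || cin == 3) {
            int apex = -1;
            for (int c = 0; c < 4; c++)
              if ((cin == 1 && tv[c]) || (cin == 3 && !tv[c])) apex = c;
            int m[3], q = 0;
            for (int c = 0; c < 4; c++)
              if (c != apex) m[q++] = edgeVertex(tn[apex], tn[c]);
            addTri(acc, m[0], m[1], m[2], dir);
          } else {  // 2 in / 2 out -> planar quad (parallelogram)
            int in[2], out[2], qi = 0, qo = 0;
            for (int c = 0; c < 4; c++) (tv[c] ? in[qi++] : out[qo++]) = c;
            int m_ac = edgeVertex(tn[in[0]], tn[out[0]]);
            int m_ad = edgeVertex(tn[in[0]], tn[out[1]]);
            int m_bd = edgeVertex(tn[in[1]], tn[out[1]]);
            int m_bc = edgeVertex(tn[in[1]], tn[out[0]]);
            addTri(acc, m_ac, m_ad, m_bd, dir);
            addTri(acc, m_ac, m_bd, m_bc, dir);
          }
        }
      }

  int nv = (int)acc.vx.size(), nt = (int)acc.tri.size() / 3;
  NumericMatrix verts(nv, 3);
  for (int i = 0; i < nv; i++) {
    verts(i, 0) = acc.vx[i]; verts(i, 1) = acc.vy[i]; verts(i, 2) = acc.vz[i];
  }
  IntegerMatrix tris(nt, 3);
  for (int i = 0; i < nt; i++) {
    tris(i, 0) = acc.tri[3 * i] + 1;      // 1-based for R
    tris(i, 1) = acc.tri[3 * i + 1] + 1;
    tris(i, 2) = acc.tri[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = verts, _["triangles"] = tris);
}

// ---------------------------------------------------------------------------
// Point-to-triangle distance (Ericson, Real-Time Collision Detection 5.1.5)
// ---------------------------------------------------------------------------
static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

static double pointTriDist2(const double p[3], const double a[3],
                            const double b[3], const double c[3]) {
  double ab[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
  double ac[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
  double ap[3] = {p[0]-a[0], p[1]-a[1], p[2]-a[2]};
  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  double q[3];
  if (d1 <= 0 && d2 <= 0) { q[0]=a[0]; q[1]=a[1]; q[2]=a[2]; goto done; }
  {
    double bp[3] = {p[0]-b[0], p[1]-b[1], p[2]-b[2]};
    double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
    if (d3 >= 0 && d4 <= d3) { q[0]=b[0]; q[1]=b[1]; q[2]=b[2]; goto done; }
    double vc = d1 * d4 - d3 * d2;
    if (vc <= 0 && d1 >= 0 && d3 <= 0) {
      double t = d1 / (d1 - d3);
      for (int i = 0; i < 3; i++) q[i] = a[i] + t * ab[i];
      goto done;
    }
    double cp[3] = {p[0]-c[0], p[1]-c[1], p[2]-c[2]};
    double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
    if (d6 >= 0 && d5 <= d6) { q[0]=c[0]; q[1]=c[1]; q[2]=c[2]; goto done; }
    double vb = d5 * d2 - d1 * d6;
    if (vb <= 0 && d2 >= 0 && d6 <= 0) {
      double t = d2 / (d2 - d6);
      for (int i = 0; i < 3; i++) q[i] = a[i] + t * ac[i];
      goto done;
    }
    double va = d3 * d6 - d5 * d4;
    if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
      double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
      for (int i = 0; i < 3; i++) q[i] = b[i] + t * (c[i] - b[i]);
      goto done;
    }
    {
      double denom = 1.0 / (va + vb + vc);
      double v = vb * denom, w = vc * denom;
      for (int i = 0; i < 3; i++) q[i] = a[i] + ab[i] * v + ac[i] * w;
    }
  }
done:
  double dx = p[0]-q[0], dy = p[1]-q[1], dz = p[2]-q[2];
  return dx*dx + dy*dy + dz*dz;
}

static inline void getTriVerts(const NumericMatrix& V, const IntegerMatrix& T,
                               int t, double a[3], double b[3], double c[3]) {
  int ia = T(t, 0) - 1, ib = T(t, 1) - 1, ic = T(t, 2) - 1;
  for (int i = 0; i < 3; i++) {
    a[i] = V(ia, i); b[i] = V(ib, i); c[i] = V(ic, i);
  }
}

// Exhaustive nearest-triangle distances: for each query point the minimum
// Euclidean distance to any triangle of the mesh.  The independent oracle.
// [[Rcpp::export(name = ".cppSurfDistBrute")]]
NumericVector cppSurfDistBrute(NumericMatrix pts, NumericMatrix verts,
                               IntegerMatrix tris) {
  int np = pts.nrow(), nt = tris.nrow();
  NumericVector out(np);
  for (int i = 0; i < np; i++) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double best = R_PosInf;
    for (int t = 0; t < nt; t++) {
      double a[3], b[3], c[3];
      getTriVerts(verts, tris, t, a, b, c);
      double d2 = pointTriDist2(p, a, b, c);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Uniform-grid accelerated nearest-triangle distances.  Triangles are binned
// by axis-aligned bounding box; queries search outward ring by ring and stop
// once the nearest unsearched ring cannot beat the current best.
// [[Rcpp::export(name = ".cppSurfDistGrid")]]
NumericVector cppSurfDistGrid(NumericMatrix pts, NumericMatrix verts,
                              IntegerMatrix tris, double cell) {
  int np = pts.nrow(), nt = tris.nrow();
  NumericVector out(np);
  if (nt == 0) { std::fill(out.begin(), out.end(), R_PosInf); return out; }
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < verts.nrow(); i++)
    for (int c = 0; c < 3; c++) {
      lo[c] = std::min(lo[c], verts(i, c));
      hi[c] = std::max(hi[c], verts(i, c));
    }
  int g[3];
  for (int c = 0; c < 3; c++) {
    g[c] = std::max(1, (int)std::ceil((hi[c] - lo[c]) / cell));
    if (g[c] > 256) g[c] = 256;
  }
  double cw[3];
  for (int c = 0; c < 3; c++) cw[c] = std::max((hi[c] - lo[c]) / g[c], 1e-12);
  auto cellOf = [&](double x, int c) {
    int i = (int)((x - lo[c]) / cw[c]);
    return std::min(std::max(i, 0), g[c] - 1);
  };
  std::vector<std::vector<int>> bins((size_t)g[0] * g[1] * g[2]);
  for (int t = 0; t < nt; t++) {
    double a[3], b[3], c[3];
    getTriVerts(verts, tris, t, a, b, c);
    int i0[3], i1[3];
    for (int cc = 0; cc < 3; cc++) {
      double mn = std::min(a[cc], std::min(b[cc], c[cc]));
      double mx = std::max(a[cc], std::max(b[cc], c[cc]));
      i0[cc] = cellOf(mn, cc); i1[cc] = cellOf(mx, cc);
    }
    for (int z = i0[2]; z <= i1[2]; z++)
      for (int y = i0[1]; y <= i1[1]; y++)
        for (int x = i0[0]; x <= i1[0]; x++)
          bins[x + (size_t)g[0] * (y + (size_t)g[1] * z)].push_back(t);
  }
  double cmin = std::min(cw[0], std::min(cw[1], cw[2]));
  int rmax = std::max(g[0], std::max(g[1], g[2]));
  for (int i = 0; i < np; i++) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    int cx = cellOf(p[0], 0), cy = cellOf(p[1], 1), cz = cellOf(p[2], 2);
    double best = R_PosInf;
    for (int r = 0; r <= rmax; r++) {
      if (best < R_PosInf && (r - 1) * cmin > std::sqrt(best)) break;
      bool any = false;
      for (int z = cz - r; z <= cz + r; z++) {
        if (z < 0 || z >= g[2]) continue;
        for (int y = cy - r; y <= cy + r; y++) {
          if (y < 0 || y >= g[1]) continue;
          for (int x = cx - r; x <= cx + r; x++) {
            if (x < 0 || x >= g[0]) continue;
            // ring shell only
            if (std::max(std::abs(x - cx),
                         std::max(std::abs(y - cy), std::abs(z - cz))) != r)
              continue;
            any = true;
            const std::vector<int>& B =
              bins[x + (size_t)g[0] * (y + (size_t)g[1] * z)];
            for (size_t q = 0; q < B.size(); q++) {
              double a[3], b[3], c[3];
              getTriVerts(verts, tris, B[q], a, b, c);
              double d2 = pointTriDist2(p, a, b, c);
              if (d2 < best) best = d2;
            }
          }
        }
      }
      if (!any && r > rmax) break;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Even-odd voxelization of a closed mesh given in continuous 0-based grid
// index coordinates.  Rays run along +z through (i+ex, j+ey); a node (i,j,k)
// is inside iff an odd number of triangle crossings lie below z = k.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".cppVoxelize")]]
IntegerVector cppVoxelize(NumericMatrix verts, IntegerMatrix tris,
                          IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double ex = 1.234567e-3, ey = 2.345678e-3;  // dodge edge/vertex hits
  std::vector<std::vector<double>> cross((size_t)nx * ny);
  int nt = tris.nrow();
  for (int t = 0; t < nt; t++) {
    double a[3], b[3], c[3];
    getTriVerts(verts, tris, t, a, b, c);
    double xmin = std::min(a[0], std::min(b[0], c[0]));
    double xmax = std::max(a[0], std::max(b[0], c[0]));
    double ymin = std::min(a[1], std::min(b[1], c[1]));
    double ymax = std::max(a[1], std::max(b[1], c[1]));
    int i0 = std::max(0, (int)std::ceil(xmin - ex));
    int i1 = std::min(nx - 1, (int)std::floor(xmax - ex));
    int j0 = std::max(0, (int)std::ceil(ymin - ey));
    int j1 = std::min(ny - 1, (int)std::floor(ymax - ey));
    double d0x = b[0]-a[0], d0y = b[1]-a[1];
    double d1x = c[0]-a[0], d1y = c[1]-a[1];
    double det = d0x * d1y - d1x * d0y;
    if (std::fabs(det) < 1e-14) continue;   // vertical triangle: no xy area
    for (int j = j0; j <= j1; j++)
      for (int i = i0; i <= i1; i++) {
        double px = i + ex - a[0], py = j + ey - a[1];
        double u = (px * d1y - d1x * py) / det;
        double v = (d0x * py - px * d0y) / det;
        if (u < 0 || v < 0 || u + v > 1) continue;
        double z = a[2] + u * (b[2] - a[2]) + v * (c[2] - a[2]);
        cross[(size_t)i + (size_t)nx * j].push_back(z);
      }
  }
  IntegerVector out((R_xlen_t)nx * ny * nz);
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      std::vector<double>& cz = cross[(size_t)i + (size_t)nx * j];
      if (cz.empty()) continue;
      std::sort(cz.begin(), cz.end());
      size_t idx = 0;
      int parity = 0;
      for (int k = 0; k < nz; k++) {
        while (idx < cz.size() && cz[idx] < k) { parity ^= 1; idx++; }
        if (parity)
          out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = 1;
      }
    }
  return out;
}
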