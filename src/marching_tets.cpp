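// Iso-surface extraction by marching tetrahedra. Each grid cube is split
// into the six path tetrahedra sharing the main diagonal; tetrahedra are
// clipped against the iso-level with linear interpolation along edges.
// Vertices are deduplicated by their grid edge, which makes the surface
// watertight by construction.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline int64_t edgeKey(int a, int b) {
  if (a > b) std::swap(a, b);
  return (int64_t)a * 100000000LL + b;
}

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector vol, double level) {
  IntegerVector dims = vol.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *f = vol.begin();
  auto lin = [&](int x, int y, int z) { return x + nx * (y + ny * z); };

  // the 6 path tetrahedra of a cube: {origin, +ea, +ea+eb, diagonal}
  static const int perms[6][3] = {
    {0, 1, 2}, {0, 2, 1}, {1, 0, 2}, {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};

  std::unordered_map<int64_t, int> vmap;
  std::vector<double> verts;  // x,y,z triples (0-based voxel coords)
  std::vector<int> faces;     // 1-based vertex index triples

  // orient a triangle so its normal points away from the inside point
  auto pushTri = [&](int v0, int v1, int v2, double inx, double iny,
                     double inz) {
    double ax = verts[3 * (v0 - 1)], ay = verts[3 * (v0 - 1) + 1],
           az = verts[3 * (v0 - 1) + 2];
    double bx = verts[3 * (v1 - 1)], by = verts[3 * (v1 - 1) + 1],
           bz = verts[3 * (v1 - 1) + 2];
    double cx2 = verts[3 * (v2 - 1)], cy2 = verts[3 * (v2 - 1) + 1],
           cz2 = verts[3 * (v2 - 1) + 2];
    double ux = bx - ax, uy = by - ay, uz = bz - az;
    double vx = cx2 - ax, vy = cy2 - ay, vz = cz2 - az;
    double nxn = uy * vz - uz * vy, nyn = uz * vx - ux * vz,
           nzn = ux * vy - uy * vx;
    double wx = inx - (ax + bx + cx2) / 3.0,
           wy = iny - (ay + by + cy2) / 3.0,
           wz = inz - (az + bz + cz2) / 3.0;
    if (nxn * wx + nyn * wy + nzn * wz > 0) std::swap(v1, v2);
    faces.push_back(v0); faces.push_back(v1); faces.push_back(v2);
  };

  auto edgeVertex = [&](int ia, int ib, int ax, int ay, int az,
                        int bx, int by, int bz) {
    int64_t key = edgeKey(ia, ib);
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double fa = f[ia], fb = f[ib];
    double t = (level - fa) / (fb - fa);
    if (t < 0) t = 0; if (t > 1) t = 1;
    verts.push_back(ax + t * (bx - ax));
    verts.push_back(ay + t * (by - ay));
    verts.push_back(az + t * (bz - az));
    int id = (int)(verts.size() / 3);
    vmap[key] = id;
    return id;
  };

  int cx[4], cy[4], cz[4], ci[4];
  bool in[4];
  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        // skip cubes fully inside/outside
        bool any = false, all = true;
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              bool b = f[lin(x + dx, y + dy, z + dz)] > level;
              any |= b; all &= b;
            }
        if (!any || all) continue;
        for (int p = 0; p < 6; ++p) {
          int off[3] = {0, 0, 0};
          cx[0] = x; cy[0] = y; cz[0] = z;
          for (int s = 0; s < 2; ++s) {
            off[perms[p][s]] = 1;
            cx[s + 1] = x + off[0]; cy[s + 1] = y + off[1];
            cz[s + 1] = z + off[2];
          }
          cx[3] = x + 1; cy[3] = y + 1; cz[3] = z + 1;
          int nin = 0;
          for (int s = 0; s < 4; ++s) {
            ci[s] = lin(cx[s], cy[s], cz[s]);
            in[s] = f[ci[s]] > level;
            if (in[s]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;
          int A[4], B[4], na = 0, nb = 0;
          for (int s = 0; s < 4; ++s) (in[s] ? A[na++] : B[nb++]) = s;
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? A[0] : B[0];
            int others[3], no = 0;
            for (int s = 0; s < 4; ++s) if (s != apex) others[no++] = s;
            int v0 = edgeVertex(ci[apex], ci[others[0]], cx[apex], cy[apex],
                                cz[apex], cx[others[0]], cy[others[0]],
                                cz[others[0]]);
            int v1 = edgeVertex(ci[apex], ci[others[1]], cx[apex], cy[apex],
                                cz[apex], cx[others[1]], cy[others[1]],
                                cz[others[1]]);
            int v2 = edgeVertex(ci[apex], ci[others[2]], cx[apex], cy[apex],
                                cz[apex], cx[others[2]], cy[others[2]],
                                cz[others[2]]);
            if (nin == 1)
              pushTri(v0, v1, v2, cx[apex], cy[apex], cz[apex]);
            else { // apex is the only outside corner; inside ref: others
              double mx = (cx[others[0]] + cx[others[1]] + cx[others[2]]) / 3.0;
              double my = (cy[others[0]] + cy[others[1]] + cy[others[2]]) / 3.0;
              double mz = (cz[others[0]] + cz[others[1]] + cz[others[2]]) / 3.0;
              pushTri(v0, v1, v2, mx, my, mz);
            }
          } else { // 2 in, 2 out: quad across four edges
            int a0 = A[0], a1 = A[1], b0 = B[0], b1 = B[1];
            int v0 = edgeVertex(ci[a0], ci[b0], cx[a0], cy[a0], cz[a0],
                                cx[b0], cy[b0], cz[b0]);
            int v1 = edgeVertex(ci[a0], ci[b1], cx[a0], cy[a0], cz[a0],
                                cx[b1], cy[b1], cz[b1]);
            int v2 = edgeVertex(ci[a1], ci[b1], cx[a1], cy[a1], cz[a1],
                                cx[b1], cy[b1], cz[b1]);
            int v3 = edgeVertex(ci[a1], ci[b0], cx[a1], cy[a1], cz[a1],
                                cx[b0], cy[b0], cz[b0]);
            double mx = (cx[a0] + cx[a1]) / 2.0,
                   my = (cy[a0] + cy[a1]) / 2.0,
                   mz = (cz[a0] + cz[a1]) / 2.0;
            pushTri(v0, v1, v2, mx, my, mz);
            pushTri(v0, v2, v3, mx, my, mz);
          }
        }
      }

  int nv = (int)(verts.size() / 3), nf = (int)(faces.size() / 3);
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = verts[3 * i]; V(i, 1) = verts[3 * i + 1];
    V(i, 2) = verts[3 * i + 2];
  }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = faces[3 * i]; F(i, 1) = faces[3 * i + 1];
    F(i, 2) = faces[3 * i + 2];
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
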