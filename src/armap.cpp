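// Attraction-repulsion spherical parametrization. Vertices start on the
// unit sphere (radial projection of the centred mesh) and are relaxed:
// each vertex is pulled toward the centroid of its mesh neighbours and
// pushed away from nearby non-neighbours (inverse-square falloff,
// truncated at twice the mean edge length), then re-normalized to unit
// norm. Updates are synchronous; iteration stops at the cap or when the
// maximum displacement drops below `tol`.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_attraction_repulsion(NumericMatrix V0, IntegerVector adj,
                                       IntegerVector adjStart, double ca,
                                       double cr, int maxIter, double tol) {
  int n = V0.nrow();
  std::vector<double> x(n), y(n), z(n), nx(n), ny(n), nz(n);
  for (int i = 0; i < n; ++i) { x[i] = V0(i, 0); y[i] = V0(i, 1); z[i] = V0(i, 2); }

  // scratch flags: neighbours of the current vertex
  std::vector<char> nb(n, 0);

  for (int iter = 0; iter < maxIter; ++iter) {
    // mean edge length -> repulsion cutoff
    double elen = 0; long ecnt = 0;
    for (int i = 0; i < n; ++i)
      for (int t = adjStart[i]; t < adjStart[i + 1]; ++t) {
        int j = adj[t];
        double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
        elen += std::sqrt(dx * dx + dy * dy + dz * dz);
        ++ecnt;
      }
    double cutoff = 2.0 * (ecnt ? elen / ecnt : 0.5);
    double cut2 = cutoff * cutoff;
    double cell = std::max(cutoff, 1e-3);

    // spatial hash over [-1,1]^3
    std::unordered_map<int64_t, std::vector<int> > grid;
    auto cellKey = [&](double px, double py, double pz) {
      int64_t ix = (int64_t)std::floor((px + 2.0) / cell);
      int64_t iy = (int64_t)std::floor((py + 2.0) / cell);
      int64_t iz = (int64_t)std::floor((pz + 2.0) / cell);
      return (ix * 4096 + iy) * 4096 + iz;
    };
    for (int i = 0; i < n; ++i) grid[cellKey(x[i], y[i], z[i])].push_back(i);

    double maxDisp = 0;
    for (int i = 0; i < n; ++i) {
      // attraction toward the neighbour centroid
      double axx = 0, ayy = 0, azz = 0;
      int lo = adjStart[i], hi = adjStart[i + 1];
      int deg = hi - lo;
      for (int t = lo; t < hi; ++t) {
        axx += x[adj[t]]; ayy += y[adj[t]]; azz += z[adj[t]];
        nb[adj[t]] = 1;
      }
      if (deg) { axx = axx / deg - x[i]; ayy = ayy / deg - y[i]; azz = azz / deg - z[i]; }

      // repulsion from nearby non-neighbours
      double rxx = 0, ryy = 0, rzz = 0;
      int64_t ix = (int64_t)std::floor((x[i] + 2.0) / cell);
      int64_t iy = (int64_t)std::floor((y[i] + 2.0) / cell);
      int64_t iz = (int64_t)std::floor((z[i] + 2.0) / cell);
      for (int64_t dx0 = -1; dx0 <= 1; ++dx0)
        for (int64_t dy0 = -1; dy0 <= 1; ++dy0)
          for (int64_t dz0 = -1; dz0 <= 1; ++dz0) {
            int64_t key = ((ix + dx0) * 4096 + (iy + dy0)) * 4096 + (iz + dz0);
            auto it = grid.find(key);
            if (it == grid.end()) continue;
            for (int j : it->second) {
              if (j == i || nb[j]) continue;
              double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
              double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 > cut2 || d2 < 1e-12) continue;
              double w = 1.0 / (d2 + 1e-6);
              rxx += dx * w; ryy += dy * w; rzz += dz * w;
            }
          }
      // scale repulsion so its step is commensurate with the cutoff
      double rnorm = std::sqrt(rxx * rxx + ryy * ryy + rzz * rzz);
      if (rnorm > 1e-12) {
        double cap = cutoff; // at most one cutoff length before weighting
        double sc = std::min(1.0, cap / rnorm);
        rxx *= sc; ryy *= sc; rzz *= sc;
      }

      // project the total displacement onto the tangent plane so that a
      // uniform spherical mesh is a fixed point (purely radial pulls
      // vanish instead of drifting the parametrization)
      double dxs = ca * axx + cr * rxx;
      double dys = ca * ayy + cr * ryy;
      double dzs = ca * azz + cr * rzz;
      double rad = dxs * x[i] + dys * y[i] + dzs * z[i];
      dxs -= rad * x[i]; dys -= rad * y[i]; dzs -= rad * z[i];
      for (int t = lo; t < hi; ++t) nb[adj[t]] = 0;
      double px = x[i] + dxs;
      double py = y[i] + dys;
      double pz = z[i] + dzs;
      double nrm = std::sqrt(px * px + py * py + pz * pz);
      if (nrm < 1e-12) { px = x[i]; py = y[i]; pz = z[i]; nrm = 1.0; }
      nx[i] = px / nrm; ny[i] = py / nrm; nz[i] = pz / nrm;
      double ddx = nx[i] - x[i], ddy = ny[i] - y[i], ddz = nz[i] - z[i];
      double disp = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
      if (disp > maxDisp) maxDisp = disp;
    }
    x = nx; y = ny; z = nz;
    if (maxDisp < tol) break;
  }

  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double nrm = std::sqrt(x[i] * x[i] + y[i] * y[i] + z[i] * z[i]);
    out(i, 0) = x[i] / nrm; out(i, 1) = y[i] / nrm; out(i, 2) = z[i] / nrm;
  }
  return out;
}
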