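// 3D convex hull (quickhull) returning the facet half-space
// representation: outward unit normals N and offsets b with the hull
// equal to { x : N x <= b }. Input points are expected to be jittered
// slightly by the caller to break lattice degeneracies.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <array>
#include <map>
using namespace Rcpp;

struct Face {
  int a, b, c;
  double nx, ny, nz, off; // outward normal, offset
  bool alive;
  std::vector<int> outside;
};

// [[Rcpp::export]]
List cpp_quickhull(NumericMatrix P) {
  int n = P.nrow();
  if (n < 4) stop("need at least 4 points");
  const double EPS = 1e-9;

  auto sub = [&](int i, int j, double *v) {
    v[0] = P(i, 0) - P(j, 0); v[1] = P(i, 1) - P(j, 1); v[2] = P(i, 2) - P(j, 2);
  };

  // initial extreme points
  int imin = 0, imax = 0;
  for (int i = 1; i < n; ++i) {
    if (P(i, 0) < P(imin, 0)) imin = i;
    if (P(i, 0) > P(imax, 0)) imax = i;
  }
  if (imin == imax) stop("degenerate point set");
  // farthest from the line imin-imax
  double d0[3]; sub(imax, imin, d0);
  double l0 = std::sqrt(d0[0] * d0[0] + d0[1] * d0[1] + d0[2] * d0[2]);
  int i3 = -1; double best = -1;
  for (int i = 0; i < n; ++i) {
    double w[3]; sub(i, imin, w);
    double cx = d0[1] * w[2] - d0[2] * w[1];
    double cy = d0[2] * w[0] - d0[0] * w[2];
    double cz = d0[0] * w[1] - d0[1] * w[0];
    double d = std::sqrt(cx * cx + cy * cy + cz * cz) / l0;
    if (d > best) { best = d; i3 = i; }
  }
  if (best < EPS) stop("degenerate (collinear) point set");
  // farthest from the plane (imin, imax, i3)
  double u[3], v[3]; sub(imax, imin, u); sub(i3, imin, v);
  double pn[3] = {u[1] * v[2] - u[2] * v[1], u[2] * v[0] - u[0] * v[2],
                  u[0] * v[1] - u[1] * v[0]};
  double pl = std::sqrt(pn[0] * pn[0] + pn[1] * pn[1] + pn[2] * pn[2]);
  pn[0] /= pl; pn[1] /= pl; pn[2] /= pl;
  int i4 = -1; best = -1;
  for (int i = 0; i < n; ++i) {
    double w[3]; sub(i, imin, w);
    double d = std::fabs(w[0] * pn[0] + w[1] * pn[1] + w[2] * pn[2]);
    if (d > best) { best = d; i4 = i; }
  }
  if (best < EPS) stop("degenerate (coplanar) point set");

  std::vector<Face> faces;
  double cx = (P(imin, 0) + P(imax, 0) + P(i3, 0) + P(i4, 0)) / 4;
  double cy = (P(imin, 1) + P(imax, 1) + P(i3, 1) + P(i4, 1)) / 4;
  double cz = (P(imin, 2) + P(imax, 2) + P(i3, 2) + P(i4, 2)) / 4;

  auto makeFace = [&](int a, int b, int c) {
    Face F; F.a = a; F.b = b; F.c = c; F.alive = true;
    double e1[3], e2[3]; sub(b, a, e1); sub(c, a, e2);
    F.nx = e1[1] * e2[2] - e1[2] * e2[1];
    F.ny = e1[2] * e2[0] - e1[0] * e2[2];
    F.nz = e1[0] * e2[1] - e1[1] * e2[0];
    double l = std::sqrt(F.nx * F.nx + F.ny * F.ny + F.nz * F.nz);
    F.nx /= l; F.ny /= l; F.nz /= l;
    F.off = F.nx * P(a, 0) + F.ny * P(a, 1) + F.nz * P(a, 2);
    // orient outward w.r.t. the interior point
    if (F.nx * cx + F.ny * cy + F.nz * cz > F.off) {
      std::swap(F.b, F.c);
      F.nx = -F.nx; F.ny = -F.ny; F.nz = -F.nz; F.off = -F.off;
    }
    return F;
  };

  faces.push_back(makeFace(imin, imax, i3));
  faces.push_back(makeFace(imin, imax, i4));
  faces.push_back(makeFace(imin, i3, i4));
  faces.push_back(makeFace(imax, i3, i4));

  auto dist = [&](const Face &F, int i) {
    return F.nx * P(i, 0) + F.ny * P(i, 1) + F.nz * P(i, 2) - F.off;
  };

  // assign points to the first face they are outside of
  for (int i = 0; i < n; ++i)
    for (size_t fi = 0; fi < faces.size(); ++fi)
      if (dist(faces[fi], i) > EPS) { faces[fi].outside.push_back(i); break; }

  long guard = 0;
  while (true) {
    if (++guard > 100000) stop("quickhull failed to converge");
    size_t fi = faces.size();
    for (size_t fj = 0; fj < faces.size(); ++fj)
      if (faces[fj].alive && !faces[fj].outside.empty()) { fi = fj; break; }
    if (fi == faces.size()) break;
    // farthest outside point of this face
    int far = -1; double fd = -1;
    for (int i : faces[fi].outside)
      if (dist(faces[fi], i) > fd) { fd = dist(faces[fi], i); far = i; }

    // visible faces and horizon
    std::vector<int> visible;
    for (size_t fj = 0; fj < faces.size(); ++fj)
      if (faces[fj].alive && dist(faces[fj], far) > EPS)
        visible.push_back((int)fj);
    std::map<std::pair<int, int>, int> edgeCount;
    for (int fj : visible) {
      int vs[3] = {faces[fj].a, faces[fj].b, faces[fj].c};
      for (int e = 0; e < 3; ++e) {
        int p1 = vs[e], p2 = vs[(e + 1) % 3];
        if (p1 > p2) std::swap(p1, p2);
        edgeCount[{p1, p2}]++;
      }
    }
    std::vector<int> orphans;
    for (int fj : visible) {
      for (int i : faces[fj].outside)
        if (i != far) orphans.push_back(i);
      faces[fj].alive = false;
      faces[fj].outside.clear();
    }
    size_t firstNew = faces.size();
    for (auto &ec : edgeCount)
      if (ec.second == 1) // horizon edge
        faces.push_back(makeFace(ec.first.first, ec.first.second, far));
    for (int i : orphans)
      for (size_t fj = firstNew; fj < faces.size(); ++fj)
        if (dist(faces[fj], i) > EPS) { faces[fj].outside.push_back(i); break; }
  }

  int nf = 0;
  for (auto &F : faces) if (F.alive) ++nf;
  NumericMatrix N(nf, 3); NumericVector b(nf);
  IntegerMatrix tri(nf, 3);
  int k = 0;
  for (auto &F : faces)
    if (F.alive) {
      N(k, 0) = F.nx; N(k, 1) = F.ny; N(k, 2) = F.nz; b[k] = F.off;
      tri(k, 0) = F.a + 1; tri(k, 1) = F.b + 1; tri(k, 2) = F.c + 1;
      ++k;
    }
  return List::create(_["normals"] = N, _["offsets"] = b,
                      _["faces"] = tri);
}
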