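#include <Rcpp.h>
#include <cfloat>
#include <cmath>
using namespace Rcpp;

// Brute-force nearest neighbour: for each query row return the index (1-based)
// of the closest reference row and the squared distance.
// [[Rcpp::export]]
List cpp_nearest(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  IntegerVector idx(nq);
  NumericVector d2(nq);
  for (int i = 0; i < nq; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    double best = DBL_MAX; int bi = 0;
    for (int j = 0; j < nr; ++j) {
      const double dx = ref(j, 0) - qx, dy = ref(j, 1) - qy, dz = ref(j, 2) - qz;
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; bi = j; }
    }
    idx[i] = bi + 1;
    d2[i] = best;
  }
  return List::create(_["index"] = idx, _["dist2"] = d2);
}

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Squared distance from point p to triangle (a, b, c) (Eberly's region method).
static double point_tri_d2(const double *p, const double *a, const double *b,
                           const double *c) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  const double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  const double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  const double aa = ab[0] * ab[0] + ab[1] * ab[1] + ab[2] * ab[2];
  const double bb = ac[0] * ac[0] + ac[1] * ac[1] + ac[2] * ac[2];
  const double abac = ab[0] * ac[0] + ab[1] * ac[1] + ab[2] * ac[2];
  double s, t;
  const double det = aa * bb - abac * abac;
  if (det > 1e-30) {
    s = (bb * d1 - abac * d2) / det;
    t = (aa * d2 - abac * d1) / det;
  } else { s = t = -1.0; }
  if (s < 0 || t < 0 || s + t > 1) {
    // project on the three edges and clamp
    double best = DBL_MAX;
    // edge a-b
    double u = aa > 0 ? clampd(d1 / aa, 0.0, 1.0) : 0.0;
    double dx, dy, dz, d;
    dx = a[0] + u * ab[0] - p[0]; dy = a[1] + u * ab[1] - p[1]; dz = a[2] + u * ab[2] - p[2];
    d = dx * dx + dy * dy + dz * dz; if (d < best) best = d;
    // edge a-c
    u = bb > 0 ? clampd(d2 / bb, 0.0, 1.0) : 0.0;
    dx = a[0] + u * ac[0] - p[0]; dy = a[1] + u * ac[1] - p[1]; dz = a[2] + u * ac[2] - p[2];
    d = dx * dx + dy * dy + dz * dz; if (d < best) best = d;
    // edge b-c
    double bc[3] = {c[0] - b[0], c[1] - b[1], c[2] - b[2]};
    double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
    const double cc = bc[0] * bc[0] + bc[1] * bc[1] + bc[2] * bc[2];
    const double d3 = bc[0] * bp[0] + bc[1] * bp[1] + bc[2] * bp[2];
    u = cc > 0 ? clampd(d3 / cc, 0.0, 1.0) : 0.0;
    dx = b[0] + u * bc[0] - p[0]; dy = b[1] + u * bc[1] - p[1]; dz = b[2] + u * bc[2] - p[2];
    d = dx * dx + dy * dy + dz * dz; if (d < best) best = d;
    return best;
  }
  double q[3];
  for (int k = 0; k < 3; ++k) q[k] = a[k] + s * ab[k] + t * ac[k] - p[k];
  return q[0] * q[0] + q[1] * q[1] + q[2] * q[2];
}

// Unsigned point-to-surface distance from each point to a triangle mesh.
// Faces are 1-based index triples. A vertex-distance prefilter bounds the
// candidate triangle set per point.
// [[Rcpp::export]]
NumericVector cpp_point_surface_dist(NumericMatrix points, NumericMatrix verts,
                                     IntegerMatrix faces) {
  const int np = points.nrow(), nf = faces.nrow(), nv = verts.nrow();
  NumericVector out(np);
  // triangle centroids and bounding radii for pruning
  std::vector<double> cx(nf), cy(nf), cz(nf), rad(nf);
  for (int j = 0; j < nf; ++j) {
    const int ia = faces(j, 0) - 1, ib = faces(j, 1) - 1, ic = faces(j, 2) - 1;
    cx[j] = (verts(ia, 0) + verts(ib, 0) + verts(ic, 0)) / 3.0;
    cy[j] = (verts(ia, 1) + verts(ib, 1) + verts(ic, 1)) / 3.0;
    cz[j] = (verts(ia, 2) + verts(ib, 2) + verts(ic, 2)) / 3.0;
    double r = 0;
    const int ids[3] = {ia, ib, ic};
    for (int k = 0; k < 3; ++k) {
      const double dx = verts(ids[k], 0) - cx[j], dy = verts(ids[k], 1) - cy[j],
                   dz = verts(ids[k], 2) - cz[j];
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d > r) r = d;
    }
    rad[j] = r;
  }
  for (int i = 0; i < np; ++i) {
    const double p[3] = {points(i, 0), points(i, 1), points(i, 2)};
    // upper bound from nearest vertex
    double ub = DBL_MAX;
    for (int v = 0; v < nv; ++v) {
      const double dx = verts(v, 0) - p[0], dy = verts(v, 1) - p[1], dz = verts(v, 2) - p[2];
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < ub) ub = d;
    }
    double best = ub;  // nearest vertex is attainable on the surface
    const double ubr = std::sqrt(ub);
    for (int j = 0; j < nf; ++j) {
      const double dx = cx[j] - p[0], dy = cy[j] - p[1], dz = cz[j] - p[2];
      const double dc = std::sqrt(dx * dx + dy * dy + dz * dz) - rad[j];
      if (dc > ubr) continue;  // triangle cannot beat current bound
      double a[3], b[3], c[3];
      const int ia = faces(j, 0) - 1, ib = faces(j, 1) - 1, ic = faces(j, 2) - 1;
      for (int k = 0; k < 3; ++k) { a[k] = verts(ia, k); b[k] = verts(ib, k); c[k] = verts(ic, k); }
      const double d = point_tri_d2(p, a, b, c);
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
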