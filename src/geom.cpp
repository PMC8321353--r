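#include <Rcpp.h>
using namespace Rcpp;

// Separating-axis test for two 2D triangles: returns true only for overlap
// with positive area. Touching along an edge or vertex (gap <= tol) counts
// as NOT overlapping, so adjacent mesh faces never occlude each other.
static bool tri_overlap(const double *ax, const double *ay,
                        const double *bx, const double *by, double tol) {
  double mingap = R_PosInf;
  const double *xs[2] = {ax, bx};
  const double *ys[2] = {ay, by};
  for (int t = 0; t < 2; ++t) {
    const double *x = xs[t], *y = ys[t];
    for (int e = 0; e < 3; ++e) {
      int e2 = (e + 1) % 3;
      // outward? direction irrelevant: axis = edge normal
      double nx = -(y[e2] - y[e]);
      double ny = x[e2] - x[e];
      double len = std::sqrt(nx * nx + ny * ny);
      if (len < 1e-300) continue;
      nx /= len; ny /= len;
      double amin = R_PosInf, amax = R_NegInf, bmin = R_PosInf, bmax = R_NegInf;
      for (int k = 0; k < 3; ++k) {
        double pa = nx * ax[k] + ny * ay[k];
        double pb = nx * bx[k] + ny * by[k];
        if (pa < amin) amin = pa;
        if (pa > amax) amax = pa;
        if (pb < bmin) bmin = pb;
        if (pb > bmax) bmax = pb;
      }
      double gap = std::min(amax, bmax) - std::max(amin, bmin);
      if (gap < mingap) mingap = gap;
      if (mingap <= tol) return false;
    }
  }
  return mingap > tol;
}

// tri: n x 6 matrices of image-space triangles (x1,y1,x2,y2,x3,y3);
// pairs: m x 2 1-based row indices. Returns logical overlap per pair.
// [[Rcpp::export]]
LogicalVector tri_overlap_pairs(NumericMatrix tri, IntegerMatrix pairs,
                                double tol) {
  int m = pairs.nrow();
  LogicalVector out(m);
  for (int p = 0; p < m; ++p) {
    int i = pairs(p, 0) - 1, j = pairs(p, 1) - 1;
    double ax[3] = {tri(i, 0), tri(i, 2), tri(i, 4)};
    double ay[3] = {tri(i, 1), tri(i, 3), tri(i, 5)};
    double bx[3] = {tri(j, 0), tri(j, 2), tri(j, 4)};
    double by[3] = {tri(j, 1), tri(j, 3), tri(j, 5)};
    out[p] = tri_overlap(ax, ay, bx, by, tol);
  }
  return out;
}

// Moller-Trumbore segment-triangle intersection. Returns true when the open
// segment origin->target (parameter t in (tmin, 1 - tmin)) hits any mesh
// triangle other than the excluded source face.
// [[Rcpp::export]]
LogicalVector segments_blocked(NumericMatrix orig, NumericMatrix dest,
                               IntegerVector exclude,
                               NumericMatrix V, IntegerMatrix F,
                               double tmin) {
  int m = orig.nrow(), nf = F.nrow();
  LogicalVector out(m);
  std::vector<double> v0x(nf), v0y(nf), v0z(nf),
      e1x(nf), e1y(nf), e1z(nf), e2x(nf), e2y(nf), e2z(nf);
  for (int f = 0; f < nf; ++f) {
    int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
    v0x[f] = V(i0, 0); v0y[f] = V(i0, 1); v0z[f] = V(i0, 2);
    e1x[f] = V(i1, 0) - v0x[f]; e1y[f] = V(i1, 1) - v0y[f];
    e1z[f] = V(i1, 2) - v0z[f];
    e2x[f] = V(i2, 0) - v0x[f]; e2y[f] = V(i2, 1) - v0y[f];
    e2z[f] = V(i2, 2) - v0z[f];
  }
  for (int s = 0; s < m; ++s) {
    double ox = orig(s, 0), oy = orig(s, 1), oz = orig(s, 2);
    double dx = dest(s, 0) - ox, dy = dest(s, 1) - oy, dz = dest(s, 2) - oz;
    int excl = exclude[s] - 1;
    bool hit = false;
    for (int f = 0; f < nf && !hit; ++f) {
      if (f == excl) continue;
      // h = d x e2
      double hx = dy * e2z[f] - dz * e2y[f];
      double hy = dz * e2x[f] - dx * e2z[f];
      double hz = dx * e2y[f] - dy * e2x[f];
      double a = e1x[f] * hx + e1y[f] * hy + e1z[f] * hz;
      if (std::fabs(a) < 1e-300) continue;
      double inv = 1.0 / a;
      double sx = ox - v0x[f], sy = oy - v0y[f], sz = oz - v0z[f];
      double u = (sx * hx + sy * hy + sz * hz) * inv;
      if (u < 0.0 || u > 1.0) continue;
      // q = s x e1
      double qx = sy * e1z[f] - sz * e1y[f];
      double qy = sz * e1x[f] - sx * e1z[f];
      double qz = sx * e1y[f] - sy * e1x[f];
      double v = (dx * qx + dy * qy + dz * qz) * inv;
      if (v < 0.0 || u + v > 1.0) continue;
      double t = (e2x[f] * qx + e2y[f] * qy + e2z[f] * qz) * inv;
      if (t > tmin && t < 1.0 - tmin) hit = true;
    }
    out[s] = hit;
  }
  return out;
}
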