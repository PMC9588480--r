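// Incremental (Bowyer-Watson) Delaunay tetrahedralisation.
//
// Scope: point sets of a few thousand soma coordinates.  The insertion step
// scans all live tetrahedra (no point-location structure), giving O(n * T)
// behaviour that is ample at this scale.  Robustness relies on a tiny
// deterministic symbolic jitter applied by the R caller to break exact
// cosphericality (regular grids, cube corners); circumsphere tests are plain
// double arithmetic.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <array>
#include <cmath>
using namespace Rcpp;

namespace {

struct Tet {
  int v[4];
  double cx, cy, cz, r2; // circumsphere
  bool dead;
};

// Circumsphere of 4 points; returns false when the tetrahedron is (near)
// degenerate, in which case the sphere is treated as unbounded.
bool circumsphere(const double* X, const double* Y, const double* Z,
                  int a, int b, int c, int d,
                  double& cx, double& cy, double& cz, double& r2,
                  double scale) {
  const double ax = X[a], ay = Y[a], az = Z[a];
  double m[3][3], rhs[3];
  const int idx[3] = {b, c, d};
  for (int k = 0; k < 3; ++k) {
    const int p = idx[k];
    m[k][0] = X[p] - ax; m[k][1] = Y[p] - ay; m[k][2] = Z[p] - az;
    rhs[k] = 0.5 * (m[k][0]*m[k][0] + m[k][1]*m[k][1] + m[k][2]*m[k][2]);
  }
  const double det =
      m[0][0]*(m[1][1]*m[2][2] - m[1][2]*m[2][1])
    - m[0][1]*(m[1][0]*m[2][2] - m[1][2]*m[2][0])
    + m[0][2]*(m[1][0]*m[2][1] - m[1][1]*m[2][0]);
  if (std::fabs(det) < 1e-12 * scale * scale * scale) return false;
  const double inv = 1.0 / det;
  const double ux =
      (rhs[0]*(m[1][1]*m[2][2]-m[1][2]*m[2][1])
     - m[0][1]*(rhs[1]*m[2][2]-m[1][2]*rhs[2])
     + m[0][2]*(rhs[1]*m[2][1]-m[1][1]*rhs[2])) * inv;
  const double uy =
      (m[0][0]*(rhs[1]*m[2][2]-m[1][2]*rhs[2])
     - rhs[0]*(m[1][0]*m[2][2]-m[1][2]*m[2][0])
     + m[0][2]*(m[1][0]*rhs[2]-rhs[1]*m[2][0])) * inv;
  const double uz =
      (m[0][0]*(m[1][1]*rhs[2]-rhs[1]*m[2][1])
     - m[0][1]*(m[1][0]*rhs[2]-rhs[1]*m[2][0])
     + rhs[0]*(m[1][0]*m[2][1]-m[1][1]*m[2][0])) * inv;
  cx = ax + ux; cy = ay + uy; cz = az + uz;
  r2 = ux*ux + uy*uy + uz*uz;
  return true;
}

typedef std::array<int,3> Face;

Face make_face(int a, int b, int c) {
  Face f = {a, b, c};
  if (f[0] > f[1]) std::swap(f[0], f[1]);
  if (f[1] > f[2]) std::swap(f[1], f[2]);
  if (f[0] > f[1]) std::swap(f[0], f[1]);
  return f;
}

} // namespace

// Returns a list with the tetrahedra (1-based vertex indices, one row each)
// and their circumradii (um).  Input coordinates are expected pre-jittered.
// [[Rcpp::export]]
List cpp_delaunay3d(NumericVector x, NumericVector y, NumericVector z) {
  const int n = x.size();
  if (n < 4) stop("at least 4 points are required");

  // working copies with 4 super-tet vertices appended
  std::vector<double> X(x.begin(), x.end()),
                      Y(y.begin(), y.end()),
                      Z(z.begin(), z.end());
  double lo[3] = {X[0], Y[0], Z[0]}, hi[3] = {X[0], Y[0], Z[0]};
  for (int i = 0; i < n; ++i) {
    lo[0] = std::min(lo[0], X[i]); hi[0] = std::max(hi[0], X[i]);
    lo[1] = std::min(lo[1], Y[i]); hi[1] = std::max(hi[1], Y[i]);
    lo[2] = std::min(lo[2], Z[i]); hi[2] = std::max(hi[2], Z[i]);
  }
  const double scale = std::max({hi[0]-lo[0], hi[1]-lo[1], hi[2]-lo[2], 1.0});
  const double cx0 = 0.5*(lo[0]+hi[0]), cy0 = 0.5*(lo[1]+hi[1]),
               cz0 = 0.5*(lo[2]+hi[2]);
  const double L = 50.0 * scale;
  // big tetrahedron {x,y,z >= c-L, x+y+z <= c+3L} contains the data cloud
  X.push_back(cx0 - L);     Y.push_back(cy0 - L);     Z.push_back(cz0 - L);
  X.push_back(cx0 + 4.0*L); Y.push_back(cy0 - L);     Z.push_back(cz0 - L);
  X.push_back(cx0 - L);     Y.push_back(cy0 + 4.0*L); Z.push_back(cz0 - L);
  X.push_back(cx0 - L);     Y.push_back(cy0 - L);     Z.push_back(cz0 + 4.0*L);

  std::vector<Tet> tets;
  {
    Tet t; t.v[0] = n; t.v[1] = n+1; t.v[2] = n+2; t.v[3] = n+3; t.dead = false;
    if (!circumsphere(X.data(), Y.data(), Z.data(), n, n+1, n+2, n+3,
                      t.cx, t.cy, t.cz, t.r2, scale))
      stop("internal error: degenerate super-tetrahedron");
    tets.push_back(t);
  }

  std::vector<int> bad;
  std::map<Face, std::pair<int,int> > faces; // face -> (count, opposite vertex)

  for (int p = 0; p < n; ++p) {
    bad.clear();
    for (int t = 0; t < (int)tets.size(); ++t) {
      if (tets[t].dead) continue;
      const double dx = X[p]-tets[t].cx, dy = Y[p]-tets[t].cy,
                   dz = Z[p]-tets[t].cz;
      if (dx*dx + dy*dy + dz*dz < tets[t].r2) bad.push_back(t);
    }
    if (bad.empty()) stop("insertion failed (degenerate input?)");
    faces.clear();
    for (int bi : bad) {
      const int* v = tets[bi].v;
      const int opp[4][3] = {{1,2,3},{0,2,3},{0,1,3},{0,1,2}};
      for (int f = 0; f < 4; ++f) {
        Face fc = make_face(v[opp[f][0]], v[opp[f][1]], v[opp[f][2]]);
        std::map<Face, std::pair<int,int> >::iterator it = faces.find(fc);
        if (it == faces.end()) faces[fc] = std::make_pair(1, v[f]);
        else it->second.first += 1;
      }
      tets[bi].dead = true;
    }
    for (std::map<Face, std::pair<int,int> >::const_iterator it = faces.begin();
         it != faces.end(); ++it) {
      if (it->second.first != 1) continue; // interior face of the cavity
      Tet t;
      t.v[0] = p; t.v[1] = it->first[0]; t.v[2] = it->first[1];
      t.v[3] = it->first[2];
      t.dead = false;
      if (!circumsphere(X.data(), Y.data(), Z.data(),
                        t.v[0], t.v[1], t.v[2], t.v[3],
                        t.cx, t.cy, t.cz, t.r2, scale)) {
        // sliver: give it an unbounded circumsphere so a later insertion
        // removes it; it contributes ~zero volume meanwhile
        t.cx = X[p]; t.cy = Y[p]; t.cz = Z[p]; t.r2 = 1e300;
      }
      tets.push_back(t);
    }
  }

  // keep tetrahedra with no super vertex
  std::vector<int> keep;
  for (int t = 0; t < (int)tets.size(); ++t) {
    if (tets[t].dead) continue;
    bool super = false;
    for (int k = 0; k < 4; ++k) if (tets[t].v[k] >= n) super = true;
    if (!super) keep.push_back(t);
  }
  const int m = keep.size();
  if (m == 0) stop("no tetrahedra produced (degenerate input?)");
  IntegerMatrix out(m, 4);
  NumericVector rad(m);
  for (int i = 0; i < m; ++i) {
    const Tet& t = tets[keep[i]];
    for (int k = 0; k < 4; ++k) out(i, k) = t.v[k] + 1;
    rad[i] = (t.r2 < 1e299) ? std::sqrt(t.r2) : R_PosInf;
  }
  return List::create(_["tets"] = out, _["circumradius_um"] = rad);
}

// Signed-tet volumes, one per row of `tets` (1-based indices into x/y/z).
// [[Rcpp::export]]
NumericVector cpp_tet_volumes(NumericVector x, NumericVector y, NumericVector z,
                              IntegerMatrix tets) {
  const int m = tets.nrow();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    const int a = tets(i,0)-1, b = tets(i,1)-1, c = tets(i,2)-1,
              d = tets(i,3)-1;
    const double bx = x[b]-x[a], by = y[b]-y[a], bz = z[b]-z[a];
    const double cx = x[c]-x[a], cy = y[c]-y[a], cz = z[c]-z[a];
    const double dx = x[d]-x[a], dy = y[d]-y[a], dz = z[d]-z[a];
    out[i] = (bx*(cy*dz - cz*dy) - by*(cx*dz - cz*dx) + bz*(cx*dy - cy*dx))
             / 6.0;
  }
  return out;
}

// Membership test against a union of tetrahedra (barycentric, boundary
// counts as inside via tolerance).
// [[Rcpp::export]]
LogicalVector cpp_point_in_tets(NumericMatrix q,
                                NumericVector x, NumericVector y,
                                NumericVector z, IntegerMatrix tets) {
  const int nq = q.nrow(), m = tets.nrow();
  LogicalVector out(nq);
  // precompute inverse edge matrices
  std::vector<double> inv(9*m), ox(m), oy(m), oz(m);
  std::vector<bool> ok(m);
  for (int i = 0; i < m; ++i) {
    const int a = tets(i,0)-1, b = tets(i,1)-1, c = tets(i,2)-1,
              d = tets(i,3)-1;
    const double m00 = x[b]-x[a], m01 = x[c]-x[a], m02 = x[d]-x[a];
    const double m10 = y[b]-y[a], m11 = y[c]-y[a], m12 = y[d]-y[a];
    const double m20 = z[b]-z[a], m21 = z[c]-z[a], m22 = z[d]-z[a];
    const double det = m00*(m11*m22-m12*m21) - m01*(m10*m22-m12*m20)
                     + m02*(m10*m21-m11*m20);
    ok[i] = std::fabs(det) > 0.0;
    if (!ok[i]) continue;
    const double id = 1.0/det;
    double* v = &inv[9*i];
    v[0] = (m11*m22-m12*m21)*id; v[1] = (m02*m21-m01*m22)*id;
    v[2] = (m01*m12-m02*m11)*id;
    v[3] = (m12*m20-m10*m22)*id; v[4] = (m00*m22-m02*m20)*id;
    v[5] = (m02*m10-m00*m12)*id;
    v[6] = (m10*m21-m11*m20)*id; v[7] = (m01*m20-m00*m21)*id;
    v[8] = (m00*m11-m01*m10)*id;
    ox[i] = x[a]; oy[i] = y[a]; oz[i] = z[a];
  }
  // barycentric slack; absorbs the symbolic jitter applied by the R caller
  const double tol = 1e-7;
  for (int j = 0; j < nq; ++j) {
    bool inside = false;
    const double px = q(j,0), py = q(j,1), pz = q(j,2);
    for (int i = 0; i < m && !inside; ++i) {
      if (!ok[i]) continue;
      const double* v = &inv[9*i];
      const double rx = px-ox[i], ry = py-oy[i], rz = pz-oz[i];
      const double b1 = v[0]*rx + v[1]*ry + v[2]*rz;
      if (b1 < -tol || b1 > 1.0+tol) continue;
      const double b2 = v[3]*rx + v[4]*ry + v[5]*rz;
      if (b2 < -tol || b1 + b2 > 1.0+tol) continue;
      const double b3 = v[6]*rx + v[7]*ry + v[8]*rz;
      if (b3 < -tol || b1 + b2 + b3 > 1.0+tol) continue;
      inside = true;
    }
    out[j] = inside;
  }
  return out;
}

// Ray-parity membership for a watertight triangle mesh.  The ray direction
// is fixed and slightly irrational to avoid edge-grazing at axis-aligned
// meshes; deterministic for any finite query point.
// [[Rcpp::export]]
LogicalVector cpp_point_in_mesh(NumericMatrix q, NumericMatrix verts,
                                IntegerMatrix faces) {
  const int nq = q.nrow(), nf = faces.nrow();
  LogicalVector out(nq);
  const double dx = 0.577350269189626, dy = 0.577350269189001,
               dz = 0.577350269190251; // ~unit, incommensurate components
  for (int j = 0; j < nq; ++j) {
    const double ox = q(j,0), oy = q(j,1), oz = q(j,2);
    int crossings = 0;
    bool on_surface = false;
    for (int f = 0; f < nf && !on_surface; ++f) {
      const int a = faces(f,0)-1, b = faces(f,1)-1, c = faces(f,2)-1;
      const double e1x = verts(b,0)-verts(a,0), e1y = verts(b,1)-verts(a,1),
                   e1z = verts(b,2)-verts(a,2);
      const double e2x = verts(c,0)-verts(a,0), e2y = verts(c,1)-verts(a,1),
                   e2z = verts(c,2)-verts(a,2);
      // Moller-Trumbore
      const double px = dy*e2z - dz*e2y, py = dz*e2x - dx*e2z,
                   pz = dx*e2y - dy*e2x;
      const double det = e1x*px + e1y*py + e1z*pz;
      if (std::fabs(det) < 1e-300) continue;
      const double inv = 1.0/det;
      const double tx = ox-verts(a,0), ty = oy-verts(a,1), tz = oz-verts(a,2);
      const double u = (tx*px + ty*py + tz*pz)*inv;
      if (u < 0.0 || u > 1.0) continue;
      const double qx = ty*e1z - tz*e1y, qy = tz*e1x - tx*e1z,
                   qz = tx*e1y - ty*e1x;
      const double v = (dx*qx + dy*qy + dz*qz)*inv;
      if (v < 0.0 || u + v > 1.0) continue;
      const double t = (e2x*qx + e2y*qy + e2z*qz)*inv;
      if (std::fabs(t) < 1e-9) { on_surface = true; break; }
      if (t > 0.0) ++crossings;
    }
    out[j] = on_surface || (crossings % 2 == 1);
  }
  return out;
}
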