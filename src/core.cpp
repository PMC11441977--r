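// Geometry core: voxelisation of triangulated surfaces, digital topology,
// iso-surface extraction, convex hull, mesh predicates.
//
// All faces are 0-based index matrices here; R wrappers convert from 1-based.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <unordered_map>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// small vector helpers
// ---------------------------------------------------------------------------
struct V3 {
  double x, y, z;
};
static inline V3 v3(double x, double y, double z) { return V3{x, y, z}; }
static inline V3 sub(const V3 &a, const V3 &b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 add(const V3 &a, const V3 &b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 mul(const V3 &a, double s) { return v3(a.x * s, a.y * s, a.z * s); }
static inline double dot(const V3 &a, const V3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(const V3 &a, const V3 &b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm3(const V3 &a) { return std::sqrt(dot(a, a)); }

static inline V3 row3(const NumericMatrix &M, int i) {
  return v3(M(i, 0), M(i, 1), M(i, 2));
}

// ---------------------------------------------------------------------------
// triangle-box overlap (Akenine-Moller separating axis test)
// box given by centre c and half-size h (axis aligned)
// ---------------------------------------------------------------------------
// Touching counts as overlap here; callers control strict vs inclusive
// semantics by shrinking or expanding the half-size h.
static bool tri_box_overlap(const V3 &c, const V3 &h, V3 t0, V3 t1, V3 t2) {
  t0 = sub(t0, c); t1 = sub(t1, c); t2 = sub(t2, c);
  // 1. box axes
  if (std::min({t0.x, t1.x, t2.x}) > h.x || std::max({t0.x, t1.x, t2.x}) < -h.x) return false;
  if (std::min({t0.y, t1.y, t2.y}) > h.y || std::max({t0.y, t1.y, t2.y}) < -h.y) return false;
  if (std::min({t0.z, t1.z, t2.z}) > h.z || std::max({t0.z, t1.z, t2.z}) < -h.z) return false;
  // 2. triangle plane
  V3 e0 = sub(t1, t0), e1 = sub(t2, t1), e2 = sub(t0, t2);
  V3 n = cross(e0, e1);
  double d = dot(n, t0);
  double r = h.x * std::fabs(n.x) + h.y * std::fabs(n.y) + h.z * std::fabs(n.z);
  if (std::fabs(d) > r) return false;
  // 3. nine cross-product axes
  const V3 *edges[3] = {&e0, &e1, &e2};
  const V3 *verts[3] = {&t0, &t1, &t2};
  for (int ie = 0; ie < 3; ie++) {
    const V3 &e = *edges[ie];
    {
      // a = (0, -e.z, e.y)
      double p0 = -e.z * verts[0]->y + e.y * verts[0]->z;
      double p1 = -e.z * verts[1]->y + e.y * verts[1]->z;
      double p2 = -e.z * verts[2]->y + e.y * verts[2]->z;
      double rr = h.y * std::fabs(e.z) + h.z * std::fabs(e.y);
      if (std::min({p0, p1, p2}) > rr || std::max({p0, p1, p2}) < -rr) return false;
    }
    {
      // a = (e.z, 0, -e.x)
      double p0 = e.z * verts[0]->x - e.x * verts[0]->z;
      double p1 = e.z * verts[1]->x - e.x * verts[1]->z;
      double p2 = e.z * verts[2]->x - e.x * verts[2]->z;
      double rr = h.x * std::fabs(e.z) + h.z * std::fabs(e.x);
      if (std::min({p0, p1, p2}) > rr || std::max({p0, p1, p2}) < -rr) return false;
    }
    {
      // a = (-e.y, e.x, 0)
      double p0 = -e.y * verts[0]->x + e.x * verts[0]->y;
      double p1 = -e.y * verts[1]->x + e.x * verts[1]->y;
      double p2 = -e.y * verts[2]->x + e.x * verts[2]->y;
      double rr = h.x * std::fabs(e.y) + h.y * std::fabs(e.x);
      if (std::min({p0, p1, p2}) > rr || std::max({p0, p1, p2}) < -rr) return false;
    }
  }
  return true;
}

// ---------------------------------------------------------------------------
// ray casting (Moller-Trumbore) with deterministic retry directions
// ---------------------------------------------------------------------------
static V3 ray_dir(int k) {
  // fixed, irrational-ish directions; deterministic across runs
  static const double dirs[8][3] = {
    {0.57735026918962573, 0.57735026918962573, 0.57735026918962573},
    {0.85065080835203999, 0.52573111211913359, 0.0},
    {0.30151134457776363, 0.90453403373329089, 0.30151134457776363},
    {0.48507125007266594, 0.72760687510899891, 0.48507125007266594},
    {0.66666666666666663, 0.33333333333333331, 0.66666666666666663},
    {0.26726124191242440, 0.53452248382484879, 0.80178372573727319},
    {0.45584230583855184, 0.56980288229818976, 0.68376345875782771},
    {0.09667364890456637, 0.77338919123653099, 0.62655656122157626}
  };
  k = k & 7;
  return v3(dirs[k][0], dirs[k][1], dirs[k][2]);
}

// returns +1 inside, 0 outside, -1 degenerate (needs retry)
static int ray_parity_once(const V3 &p, const V3 &dir,
                           const NumericMatrix &V, const IntegerMatrix &F) {
  int nf = F.nrow();
  int crossings = 0;
  const double EPS = 1e-12;
  for (int f = 0; f < nf; f++) {
    V3 a = row3(V, F(f, 0)), b = row3(V, F(f, 1)), c = row3(V, F(f, 2));
    V3 e1 = sub(b, a), e2 = sub(c, a);
    V3 pv = cross(dir, e2);
    double det = dot(e1, pv);
    if (std::fabs(det) < EPS) continue;
    double inv = 1.0 / det;
    V3 tv = sub(p, a);
    double u = dot(tv, pv) * inv;
    if (u < -1e-10 || u > 1.0 + 1e-10) continue;
    V3 qv = cross(tv, e1);
    double vv = dot(dir, qv) * inv;
    if (vv < -1e-10 || u + vv > 1.0 + 1e-10) continue;
    double t = dot(e2, qv) * inv;
    if (std::fabs(t) < 1e-10) return -1;       // point on surface: ambiguous
    if (u < 1e-9 || vv < 1e-9 || u + vv > 1.0 - 1e-9) {
      if (t > 0) return -1;                    // grazing an edge: retry
    }
    if (t > 0) crossings++;
  }
  return crossings & 1;
}

static bool point_in_mesh(const V3 &p, const NumericMatrix &V, const IntegerMatrix &F) {
  for (int k = 0; k < 8; k++) {
    int r = ray_parity_once(p, ray_dir(k), V, F);
    if (r >= 0) return r == 1;
  }
  // all directions grazed: fall back to last parity by nudging the point
  V3 q = add(p, mul(ray_dir(0), 1e-9));
  int r = ray_parity_once(q, ray_dir(1), V, F);
  return r == 1;
}

// [[Rcpp::export]]
LogicalVector cs_points_in_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  int n = P.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; i++) out[i] = point_in_mesh(row3(P, i), V, F);
  return out;
}

// ---------------------------------------------------------------------------
// voxelisation codes per voxel, with positive-measure overlap semantics:
//   1 = the open voxel intersects the surface (strict triangle-box overlap)
//   2 = the open voxel is inside the solid (no strict surface overlap,
//       centre inside)
//   0 = the open voxel is outside the solid
// Voxels merely *touched* by coplanar geometry (surface on the closed-box
// boundary only) are classified individually by centre parity: they block the
// component flood fill, because inside/outside status may change across them.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cs_voxelise_codes(NumericMatrix V, IntegerMatrix F,
                                NumericVector origin, double spacing,
                                IntegerVector dims) {
  int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  R_xlen_t nvox = (R_xlen_t)d0 * d1 * d2;
  IntegerVector codes(nvox, 0);
  std::vector<uint8_t> mark(nvox, 0); // 0 clean, 1 touch-only, 2 strict boundary
  V3 o = v3(origin[0], origin[1], origin[2]);
  double half = spacing / 2.0;
  double eps = 1e-9 * spacing;
  V3 h_strict = v3(half - eps, half - eps, half - eps);
  V3 h_touch = v3(half + eps, half + eps, half + eps);

  int nf = F.nrow();
  for (int f = 0; f < nf; f++) {
    V3 a = row3(V, F(f, 0)), b = row3(V, F(f, 1)), c = row3(V, F(f, 2));
    double lox = std::min({a.x, b.x, c.x}), hix = std::max({a.x, b.x, c.x});
    double loy = std::min({a.y, b.y, c.y}), hiy = std::max({a.y, b.y, c.y});
    double loz = std::min({a.z, b.z, c.z}), hiz = std::max({a.z, b.z, c.z});
    int i0 = std::max(0, (int)std::floor((lox - o.x) / spacing - 1e-9));
    int i1 = std::min(d0 - 1, (int)std::floor((hix - o.x) / spacing + 1e-9));
    int j0 = std::max(0, (int)std::floor((loy - o.y) / spacing - 1e-9));
    int j1 = std::min(d1 - 1, (int)std::floor((hiy - o.y) / spacing + 1e-9));
    int k0 = std::max(0, (int)std::floor((loz - o.z) / spacing - 1e-9));
    int k1 = std::min(d2 - 1, (int)std::floor((hiz - o.z) / spacing + 1e-9));
    for (int k = k0; k <= k1; k++)
      for (int j = j0; j <= j1; j++)
        for (int i = i0; i <= i1; i++) {
          R_xlen_t id = (R_xlen_t)i + (R_xlen_t)d0 * (j + (R_xlen_t)d1 * k);
          if (mark[id] == 2) continue;
          V3 cc = v3(o.x + (i + 0.5) * spacing,
                     o.y + (j + 0.5) * spacing,
                     o.z + (k + 0.5) * spacing);
          if (tri_box_overlap(cc, h_strict, a, b, c)) mark[id] = 2;
          else if (mark[id] == 0 && tri_box_overlap(cc, h_touch, a, b, c))
            mark[id] = 1;
        }
  }

  // 6-connected components over clean voxels (flood fill blocked by both
  // boundary and touch voxels); classify one representative centre each
  std::vector<int32_t> comp(nvox, -2); // -2 unvisited clean, -1 blocked
  for (R_xlen_t i = 0; i < nvox; i++) if (mark[i]) comp[i] = -1;
  int ncomp = 0;
  std::vector<R_xlen_t> rep;
  std::vector<uint8_t> touches_border;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < nvox; s++) {
    if (comp[s] != -2) continue;
    int cid = ncomp++;
    rep.push_back(s);
    touches_border.push_back(0);
    comp[s] = cid;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int i = (int)(cur % d0);
      int j = (int)((cur / d0) % d1);
      int k = (int)(cur / ((R_xlen_t)d0 * d1));
      if (i == 0 || j == 0 || k == 0 || i == d0 - 1 || j == d1 - 1 || k == d2 - 1)
        touches_border[cid] = 1;
      const int di[6] = {1, -1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, 1, -1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, 1, -1};
      for (int t = 0; t < 6; t++) {
        int ni = i + di[t], nj = j + dj[t], nk = k + dk[t];
        if (ni < 0 || nj < 0 || nk < 0 || ni >= d0 || nj >= d1 || nk >= d2) continue;
        R_xlen_t nid = (R_xlen_t)ni + (R_xlen_t)d0 * (nj + (R_xlen_t)d1 * nk);
        if (comp[nid] == -2) { comp[nid] = cid; q.push(nid); }
      }
    }
  }
  std::vector<uint8_t> inside(ncomp, 0);
  auto centre = [&](R_xlen_t s) -> V3 {
    int i = (int)(s % d0);
    int j = (int)((s / d0) % d1);
    int k = (int)(s / ((R_xlen_t)d0 * d1));
    return v3(o.x + (i + 0.5) * spacing,
              o.y + (j + 0.5) * spacing,
              o.z + (k + 0.5) * spacing);
  };
  for (int c = 0; c < ncomp; c++) {
    if (touches_border[c]) { inside[c] = 0; continue; } // grid has empty border
    inside[c] = point_in_mesh(centre(rep[c]), V, F) ? 1 : 0;
  }
  for (R_xlen_t i = 0; i < nvox; i++) {
    if (mark[i] == 2) codes[i] = 1;
    else if (mark[i] == 1) codes[i] = point_in_mesh(centre(i), V, F) ? 2 : 0;
    else codes[i] = inside[comp[i]] ? 2 : 0;
  }
  return codes;
}

// ---------------------------------------------------------------------------
// label empty voxels: 0 occupied, 1 exterior (6-conn flood from border),
// 2..k+1 cavities
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cs_label_empty(LogicalVector occ, IntegerVector dims) {
  int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  R_xlen_t nvox = (R_xlen_t)d0 * d1 * d2;
  IntegerVector lab(nvox, -1);
  for (R_xlen_t i = 0; i < nvox; i++) if (occ[i]) lab[i] = 0;
  std::queue<R_xlen_t> q;
  // seed exterior from all border voxels
  auto push_if_empty = [&](int i, int j, int k) {
    R_xlen_t id = (R_xlen_t)i + (R_xlen_t)d0 * (j + (R_xlen_t)d1 * k);
    if (lab[id] == -1) { lab[id] = 1; q.push(id); }
  };
  for (int j = 0; j < d1; j++) for (int k = 0; k < d2; k++) { push_if_empty(0, j, k); push_if_empty(d0 - 1, j, k); }
  for (int i = 0; i < d0; i++) for (int k = 0; k < d2; k++) { push_if_empty(i, 0, k); push_if_empty(i, d1 - 1, k); }
  for (int i = 0; i < d0; i++) for (int j = 0; j < d1; j++) { push_if_empty(i, j, 0); push_if_empty(i, j, d2 - 1); }
  const int di[6] = {1, -1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, 1, -1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, 1, -1};
  while (!q.empty()) {
    R_xlen_t cur = q.front(); q.pop();
    int i = (int)(cur % d0);
    int j = (int)((cur / d0) % d1);
    int k = (int)(cur / ((R_xlen_t)d0 * d1));
    for (int t = 0; t < 6; t++) {
      int ni = i + di[t], nj = j + dj[t], nk = k + dk[t];
      if (ni < 0 || nj < 0 || nk < 0 || ni >= d0 || nj >= d1 || nk >= d2) continue;
      R_xlen_t nid = (R_xlen_t)ni + (R_xlen_t)d0 * (nj + (R_xlen_t)d1 * nk);
      if (lab[nid] == -1) { lab[nid] = 1; q.push(nid); }
    }
  }
  // remaining -1 voxels are cavities
  int next = 2;
  for (R_xlen_t s = 0; s < nvox; s++) {
    if (lab[s] != -1) continue;
    int cid = next++;
    lab[s] = cid; q.push(s);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int i = (int)(cur % d0);
      int j = (int)((cur / d0) % d1);
      int k = (int)(cur / ((R_xlen_t)d0 * d1));
      for (int t = 0; t < 6; t++) {
        int ni = i + di[t], nj = j + dj[t], nk = k + dk[t];
        if (ni < 0 || nj < 0 || nk < 0 || ni >= d0 || nj >= d1 || nk >= d2) continue;
        R_xlen_t nid = (R_xlen_t)ni + (R_xlen_t)d0 * (nj + (R_xlen_t)d1 * nk);
        if (lab[nid] == -1) { lab[nid] = cid; q.push(nid); }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// connected components of an occupied set, 6 or 26 connectivity
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
int cs_count_components(LogicalVector occ, IntegerVector dims, int connectivity) {
  int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  R_xlen_t nvox = (R_xlen_t)d0 * d1 * d2;
  std::vector<int> lab(nvox, 0);
  int ncomp = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < nvox; s++) {
    if (!occ[s] || lab[s]) continue;
    ncomp++;
    lab[s] = ncomp; q.push(s);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int i = (int)(cur % d0);
      int j = (int)((cur / d0) % d1);
      int k = (int)(cur / ((R_xlen_t)d0 * d1));
      for (int dk2 = -1; dk2 <= 1; dk2++)
        for (int dj2 = -1; dj2 <= 1; dj2++)
          for (int di2 = -1; di2 <= 1; di2++) {
            int man = std::abs(di2) + std::abs(dj2) + std::abs(dk2);
            if (man == 0) continue;
            if (connectivity == 6 && man > 1) continue;
            int ni = i + di2, nj = j + dj2, nk = k + dk2;
            if (ni < 0 || nj < 0 || nk < 0 || ni >= d0 || nj >= d1 || nk >= d2) continue;
            R_xlen_t nid = (R_xlen_t)ni + (R_xlen_t)d0 * (nj + (R_xlen_t)d1 * nk);
            if (occ[nid] && !lab[nid]) { lab[nid] = ncomp; q.push(nid); }
          }
    }
  }
  return ncomp;
}

// ---------------------------------------------------------------------------
// faces-mode surface: union of voxel faces between solid and non-solid,
// outward-oriented, deduplicated lattice vertices
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cs_faces_mesh(LogicalVector solid, IntegerVector dims,
                   NumericVector origin, double spacing) {
  int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  R_xlen_t np0 = (R_xlen_t)(d0 + 1), np1 = (R_xlen_t)(d1 + 1);
  std::unordered_map<uint64_t, int> vmap;
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;
  auto vid = [&](int i, int j, int k) -> int {
    uint64_t key = (uint64_t)i + (uint64_t)np0 * ((uint64_t)j + (uint64_t)np1 * (uint64_t)k);
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    int id = (int)vx.size();
    vmap[key] = id;
    vx.push_back(origin[0] + i * spacing);
    vy.push_back(origin[1] + j * spacing);
    vz.push_back(origin[2] + k * spacing);
    return id;
  };
  auto is_solid = [&](int i, int j, int k) -> bool {
    if (i < 0 || j < 0 || k < 0 || i >= d0 || j >= d1 || k >= d2) return false;
    return solid[(R_xlen_t)i + (R_xlen_t)d0 * (j + (R_xlen_t)d1 * k)];
  };
  auto quad = [&](int a, int b, int c, int d) {
    fa.push_back(a); fb.push_back(b); fc.push_back(c);
    fa.push_back(a); fb.push_back(c); fc.push_back(d);
  };
  for (int k = 0; k < d2; k++)
    for (int j = 0; j < d1; j++)
      for (int i = 0; i < d0; i++) {
        if (!is_solid(i, j, k)) continue;
        // +x face (normal +x): ccw seen from +x
        if (!is_solid(i + 1, j, k))
          quad(vid(i + 1, j, k), vid(i + 1, j + 1, k), vid(i + 1, j + 1, k + 1), vid(i + 1, j, k + 1));
        // -x face
        if (!is_solid(i - 1, j, k))
          quad(vid(i, j, k), vid(i, j, k + 1), vid(i, j + 1, k + 1), vid(i, j + 1, k));
        // +y face
        if (!is_solid(i, j + 1, k))
          quad(vid(i, j + 1, k), vid(i, j + 1, k + 1), vid(i + 1, j + 1, k + 1), vid(i + 1, j + 1, k));
        // -y face
        if (!is_solid(i, j - 1, k))
          quad(vid(i, j, k), vid(i + 1, j, k), vid(i + 1, j, k + 1), vid(i, j, k + 1));
        // +z face
        if (!is_solid(i, j, k + 1))
          quad(vid(i, j, k + 1), vid(i + 1, j, k + 1), vid(i + 1, j + 1, k + 1), vid(i, j + 1, k + 1));
        // -z face
        if (!is_solid(i, j, k - 1))
          quad(vid(i, j, k), vid(i, j + 1, k), vid(i + 1, j + 1, k), vid(i + 1, j, k));
      }
  int nv = (int)vx.size(), nf = (int)fa.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; i++) { V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vz[i]; }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; i++) { F(i, 0) = fa[i]; F(i, 1) = fb[i]; F(i, 2) = fc[i]; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// marching tetrahedra over the voxel-centre lattice of a binary field.
// A cell is the cube between 8 neighbouring voxel centres, split into 6
// tetrahedra sharing the main diagonal; iso-vertices at edge midpoints.
// Consistent face diagonals across neighbouring cells -> watertight mesh.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cs_marching_tets(LogicalVector solid, IntegerVector dims,
                      NumericVector origin, double spacing) {
  int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  R_xlen_t nvox = (R_xlen_t)d0 * d1 * d2;
  std::unordered_map<uint64_t, int> emap; // edge (node,node) -> vertex id
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;
  auto node_id = [&](int i, int j, int k) -> R_xlen_t {
    return (R_xlen_t)i + (R_xlen_t)d0 * (j + (R_xlen_t)d1 * k);
  };
  auto node_pos = [&](R_xlen_t id) -> V3 {
    int i = (int)(id % d0);
    int j = (int)((id / d0) % d1);
    int k = (int)(id / ((R_xlen_t)d0 * d1));
    return v3(origin[0] + (i + 0.5) * spacing,
              origin[1] + (j + 0.5) * spacing,
              origin[2] + (k + 0.5) * spacing);
  };
  auto edge_vertex = [&](R_xlen_t a, R_xlen_t b) -> int {
    R_xlen_t lo = std::min(a, b), hi = std::max(a, b);
    uint64_t key = (uint64_t)lo * (uint64_t)nvox + (uint64_t)hi;
    auto it = emap.find(key);
    if (it != emap.end()) return it->second;
    V3 pa = node_pos(a), pb = node_pos(b);
    int id = (int)vx.size();
    emap[key] = id;
    vx.push_back(0.5 * (pa.x + pb.x));
    vy.push_back(0.5 * (pa.y + pb.y));
    vz.push_back(0.5 * (pa.z + pb.z));
    return id;
  };
  auto vpos = [&](int id) -> V3 { return v3(vx[id], vy[id], vz[id]); };
  // emit triangle oriented so normal points from inside toward outside
  auto emit = [&](int a, int b, int c, const V3 &in_pt, const V3 &out_pt) {
    V3 n = cross(sub(vpos(b), vpos(a)), sub(vpos(c), vpos(a)));
    if (dot(n, sub(out_pt, in_pt)) >= 0) { fa.push_back(a); fb.push_back(b); fc.push_back(c); }
    else { fa.push_back(a); fb.push_back(c); fc.push_back(b); }
  };
  // 6-tet decomposition (vertex bits: x + 2y + 4z), all sharing diagonal 0-7
  static const int TETS[6][4] = {
    {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7}, {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}
  };
  for (int k = 0; k < d2 - 1; k++)
    for (int j = 0; j < d1 - 1; j++)
      for (int i = 0; i < d0 - 1; i++) {
        R_xlen_t nid[8];
        bool val[8];
        bool any = false, all = true;
        for (int b = 0; b < 8; b++) {
          int bi = i + (b & 1), bj = j + ((b >> 1) & 1), bk = k + ((b >> 2) & 1);
          nid[b] = node_id(bi, bj, bk);
          val[b] = solid[nid[b]];
          any = any || val[b];
          all = all && val[b];
        }
        if (!any || all) continue;
        for (int t = 0; t < 6; t++) {
          R_xlen_t tn[4];
          bool tv[4];
          int nin = 0;
          for (int m = 0; m < 4; m++) {
            tn[m] = nid[TETS[t][m]];
            tv[m] = val[TETS[t][m]];
            if (tv[m]) nin++;
          }
          if (nin == 0 || nin == 4) continue;
          // centroids of inside / outside corners for orientation
          V3 cin = v3(0, 0, 0), cout = v3(0, 0, 0);
          int ni = 0, no = 0;
          for (int m = 0; m < 4; m++) {
            V3 p = node_pos(tn[m]);
            if (tv[m]) { cin = add(cin, p); ni++; } else { cout = add(cout, p); no++; }
          }
          cin = mul(cin, 1.0 / ni); cout = mul(cout, 1.0 / no);
          if (nin == 1 || nin == 3) {
            bool target = (nin == 1);
            int apex = -1;
            for (int m = 0; m < 4; m++) if (tv[m] == target) apex = m;
            int o1 = -1, o2 = -1, o3 = -1;
            for (int m = 0; m < 4; m++) if (m != apex) { if (o1 < 0) o1 = m; else if (o2 < 0) o2 = m; else o3 = m; }
            int va = edge_vertex(tn[apex], tn[o1]);
            int vb = edge_vertex(tn[apex], tn[o2]);
            int vc = edge_vertex(tn[apex], tn[o3]);
            emit(va, vb, vc, cin, cout);
          } else { // 2-2
            int in1 = -1, in2 = -1, out1 = -1, out2 = -1;
            for (int m = 0; m < 4; m++) {
              if (tv[m]) { if (in1 < 0) in1 = m; else in2 = m; }
              else { if (out1 < 0) out1 = m; else out2 = m; }
            }
            int v11 = edge_vertex(tn[in1], tn[out1]);
            int v12 = edge_vertex(tn[in1], tn[out2]);
            int v21 = edge_vertex(tn[in2], tn[out1]);
            int v22 = edge_vertex(tn[in2], tn[out2]);
            emit(v11, v21, v22, cin, cout);
            emit(v11, v22, v12, cin, cout);
          }
        }
      }
  int nv = (int)vx.size(), nf = (int)fa.size();
  NumericMatrix V(nv, 3);
  for (int m = 0; m < nv; m++) { V(m, 0) = vx[m]; V(m, 1) = vy[m]; V(m, 2) = vz[m]; }
  IntegerMatrix F(nf, 3);
  for (int m = 0; m < nf; m++) { F(m, 0) = fa[m]; F(m, 1) = fb[m]; F(m, 2) = fc[m]; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// 3D convex hull (qhull-style incremental with outside sets); returns
// surface area, enclosed volume and number of hull facets
// ---------------------------------------------------------------------------
struct HullFace {
  int a, b, c;          // point indices
  V3 n;                 // outward normal (not normalised)
  double off;           // n . x = off plane
  int nb[3];            // neighbour face across edge (a,b), (b,c), (c,a)
  std::vector<int> outside;
  bool dead = false;
};

// [[Rcpp::export]]
List cs_hull(NumericMatrix P) {
  int n = P.nrow();
  if (n < 4) stop("need at least 4 points for a 3D hull");
  std::vector<V3> pts(n);
  for (int i = 0; i < n; i++) pts[i] = row3(P, i);
  // scale for tolerance
  double ext = 0;
  for (int d = 0; d < 3; d++) {
    double lo = R_PosInf, hi = R_NegInf;
    for (int i = 0; i < n; i++) {
      double v = d == 0 ? pts[i].x : (d == 1 ? pts[i].y : pts[i].z);
      lo = std::min(lo, v); hi = std::max(hi, v);
    }
    ext = std::max(ext, hi - lo);
  }
  if (ext <= 0) stop("degenerate point set");
  const double eps = 1e-10 * ext;

  // initial simplex: extreme points
  int i0 = 0, i1 = 0;
  for (int i = 0; i < n; i++) {
    if (pts[i].x < pts[i0].x) i0 = i;
    if (pts[i].x > pts[i1].x) i1 = i;
  }
  if (i0 == i1) { i1 = (i0 + 1) % n; }
  int i2 = -1; double best = -1;
  for (int i = 0; i < n; i++) {
    V3 d = cross(sub(pts[i1], pts[i0]), sub(pts[i], pts[i0]));
    double a = norm3(d);
    if (a > best) { best = a; i2 = i; }
  }
  if (best < eps * eps) stop("degenerate (collinear) point set");
  int i3 = -1; best = -1;
  V3 n0 = cross(sub(pts[i1], pts[i0]), sub(pts[i2], pts[i0]));
  for (int i = 0; i < n; i++) {
    double d = std::fabs(dot(n0, sub(pts[i], pts[i0])));
    if (d > best) { best = d; i3 = i; }
  }
  if (best < eps * norm3(n0)) stop("degenerate (coplanar) point set");

  std::vector<HullFace> faces;
  auto mkface = [&](int a, int b, int c, const V3 &interior) -> int {
    HullFace f;
    f.a = a; f.b = b; f.c = c;
    f.n = cross(sub(pts[b], pts[a]), sub(pts[c], pts[a]));
    if (dot(f.n, sub(interior, pts[a])) > 0) { std::swap(f.b, f.c); f.n = mul(f.n, -1.0); }
    f.off = dot(f.n, pts[f.a]);
    f.nb[0] = f.nb[1] = f.nb[2] = -1;
    faces.push_back(f);
    return (int)faces.size() - 1;
  };
  V3 interior = mul(add(add(pts[i0], pts[i1]), add(pts[i2], pts[i3])), 0.25);
  int f0 = mkface(i0, i1, i2, interior);
  int f1 = mkface(i0, i1, i3, interior);
  int f2 = mkface(i0, i2, i3, interior);
  int f3 = mkface(i1, i2, i3, interior);
  // set adjacency for the simplex by brute force
  auto link_all = [&](std::vector<int> fs) {
    for (size_t x = 0; x < fs.size(); x++)
      for (size_t y = 0; y < fs.size(); y++) {
        if (x == y) continue;
        HullFace &fx = faces[fs[x]];
        const HullFace &fy = faces[fs[y]];
        int ex[3][2] = {{fx.a, fx.b}, {fx.b, fx.c}, {fx.c, fx.a}};
        int vy[3] = {fy.a, fy.b, fy.c};
        for (int e = 0; e < 3; e++) {
          int cnt = 0;
          for (int m = 0; m < 3; m++) if (vy[m] == ex[e][0] || vy[m] == ex[e][1]) cnt++;
          if (cnt == 2) fx.nb[e] = fs[y];
        }
      }
  };
  link_all({f0, f1, f2, f3});

  // assign outside sets
  std::vector<int> initial(4); initial[0] = f0; initial[1] = f1; initial[2] = f2; initial[3] = f3;
  for (int i = 0; i < n; i++) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    for (int fi : initial) {
      HullFace &f = faces[fi];
      if (dot(f.n, pts[i]) - f.off > eps * norm3(f.n)) { f.outside.push_back(i); break; }
    }
  }

  std::queue<int> pending;
  pending.push(f0); pending.push(f1); pending.push(f2); pending.push(f3);
  while (!pending.empty()) {
    int fi = pending.front(); pending.pop();
    if (fi >= (int)faces.size()) continue;
    if (faces[fi].dead || faces[fi].outside.empty()) continue;
    // furthest point
    HullFace &f = faces[fi];
    double nn = norm3(f.n);
    int p = -1; double bestd = -1;
    for (int idx : f.outside) {
      double d = dot(f.n, pts[idx]) - f.off;
      if (d > bestd) { bestd = d; p = idx; }
    }
    // find visible faces by BFS
    std::vector<int> visible;
    std::vector<char> seen(faces.size(), 0);
    std::queue<int> bq;
    bq.push(fi); seen[fi] = 1;
    while (!bq.empty()) {
      int cf = bq.front(); bq.pop();
      HullFace &g = faces[cf];
      if (dot(g.n, pts[p]) - g.off > eps * norm3(g.n)) {
        visible.push_back(cf);
        for (int e = 0; e < 3; e++) {
          int nbf = g.nb[e];
          if (nbf >= 0 && !seen[nbf] && !faces[nbf].dead) { seen[nbf] = 1; bq.push(nbf); }
        }
      }
    }
    (void)nn;
    std::vector<char> isvis(faces.size(), 0);
    for (int v : visible) isvis[v] = 1;
    // horizon edges: edges of visible faces whose neighbour is not visible
    struct HEdge { int u, v, nbface; };
    std::vector<HEdge> horizon;
    for (int vfi : visible) {
      HullFace &g = faces[vfi];
      int ev[3][2] = {{g.a, g.b}, {g.b, g.c}, {g.c, g.a}};
      for (int e = 0; e < 3; e++) {
        int nbf = g.nb[e];
        if (nbf < 0 || faces[nbf].dead) continue;
        if (!isvis[nbf]) horizon.push_back(HEdge{ev[e][0], ev[e][1], nbf});
      }
    }
    // collect orphaned outside points
    std::vector<int> orphans;
    for (int vfi : visible) {
      for (int idx : faces[vfi].outside) if (idx != p) orphans.push_back(idx);
      faces[vfi].dead = true;
      faces[vfi].outside.clear();
    }
    // build new faces: p + horizon edges (keep winding u->v so outward)
    std::unordered_map<uint64_t, std::pair<int, int>> apexEdge; // (min,max) -> (face, slot)
    std::vector<int> newfaces;
    for (const HEdge &he : horizon) {
      HullFace nf2;
      nf2.a = he.u; nf2.b = he.v; nf2.c = p;
      nf2.n = cross(sub(pts[nf2.b], pts[nf2.a]), sub(pts[nf2.c], pts[nf2.a]));
      if (dot(nf2.n, sub(interior, pts[nf2.a])) > 0) { std::swap(nf2.a, nf2.b); nf2.n = mul(nf2.n, -1.0); }
      nf2.off = dot(nf2.n, pts[nf2.a]);
      nf2.nb[0] = nf2.nb[1] = nf2.nb[2] = -1;
      faces.push_back(nf2);
      int nfi = (int)faces.size() - 1;
      newfaces.push_back(nfi);
      // link across horizon edge with surviving neighbour
      HullFace &sf = faces[nfi];
      HullFace &old = faces[he.nbface];
      int se[3][2] = {{sf.a, sf.b}, {sf.b, sf.c}, {sf.c, sf.a}};
      int oe[3][2] = {{old.a, old.b}, {old.b, old.c}, {old.c, old.a}};
      for (int e = 0; e < 3; e++) {
        bool has_u = se[e][0] == he.u || se[e][1] == he.u;
        bool has_v = se[e][0] == he.v || se[e][1] == he.v;
        if (has_u && has_v) sf.nb[e] = he.nbface;
      }
      for (int e = 0; e < 3; e++) {
        bool has_u = oe[e][0] == he.u || oe[e][1] == he.u;
        bool has_v = oe[e][0] == he.v || oe[e][1] == he.v;
        if (has_u && has_v) old.nb[e] = nfi;
      }
      // link apex edges (p, u) and (p, v) between new faces
      for (int endpt : {he.u, he.v}) {
        uint64_t key = (uint64_t)std::min(endpt, p) * (uint64_t)n + (uint64_t)std::max(endpt, p);
        int slot = -1;
        for (int e = 0; e < 3; e++) {
          bool has_p = se[e][0] == p || se[e][1] == p;
          bool has_q = se[e][0] == endpt || se[e][1] == endpt;
          if (has_p && has_q) slot = e;
        }
        auto it = apexEdge.find(key);
        if (it == apexEdge.end()) apexEdge[key] = std::make_pair(nfi, slot);
        else {
          faces[nfi].nb[slot] = it->second.first;
          faces[it->second.first].nb[it->second.second] = nfi;
        }
      }
    }
    // redistribute orphans
    for (int idx : orphans) {
      for (int nfi : newfaces) {
        HullFace &g = faces[nfi];
        if (dot(g.n, pts[idx]) - g.off > eps * norm3(g.n)) { g.outside.push_back(idx); break; }
      }
    }
    for (int nfi : newfaces) if (!faces[nfi].outside.empty()) pending.push(nfi);
  }

  double area = 0, vol = 0;
  int nfac = 0;
  for (const HullFace &f : faces) {
    if (f.dead) continue;
    nfac++;
    V3 a = pts[f.a], b = pts[f.b], c = pts[f.c];
    area += 0.5 * norm3(cross(sub(b, a), sub(c, a)));
    vol += dot(a, cross(b, c)) / 6.0;
  }
  return List::create(_["area"] = area, _["volume"] = std::fabs(vol), _["n_facets"] = nfac);
}

// ---------------------------------------------------------------------------
// distance from points to a triangle mesh (closest point on any triangle)
// ---------------------------------------------------------------------------
static double point_tri_dist2(const V3 &p, const V3 &a, const V3 &b, const V3 &c) {
  // Ericson, Real-Time Collision Detection
  V3 ab = sub(b, a), ac = sub(c, a), ap = sub(p, a);
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) { V3 d = sub(p, a); return dot(d, d); }
  V3 bp = sub(p, b);
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) { V3 d = sub(p, b); return dot(d, d); }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    V3 q = add(a, mul(ab, v)); V3 d = sub(p, q); return dot(d, d);
  }
  V3 cp = sub(p, c);
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) { V3 d = sub(p, c); return dot(d, d); }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    V3 q = add(a, mul(ac, w)); V3 d = sub(p, q); return dot(d, d);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    V3 q = add(b, mul(sub(c, b), w)); V3 d = sub(p, q); return dot(d, d);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  V3 q = add(a, add(mul(ab, v), mul(ac, w)));
  V3 d = sub(p, q);
  return dot(d, d);
}

// [[Rcpp::export]]
NumericVector cs_point_mesh_distance(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  int np = P.nrow(), nf = F.nrow();
  // precompute triangle bboxes for pruning
  std::vector<double> blo(3 * nf), bhi(3 * nf);
  for (int f = 0; f < nf; f++) {
    V3 a = row3(V, F(f, 0)), b = row3(V, F(f, 1)), c = row3(V, F(f, 2));
    blo[3 * f + 0] = std::min({a.x, b.x, c.x}); bhi[3 * f + 0] = std::max({a.x, b.x, c.x});
    blo[3 * f + 1] = std::min({a.y, b.y, c.y}); bhi[3 * f + 1] = std::max({a.y, b.y, c.y});
    blo[3 * f + 2] = std::min({a.z, b.z, c.z}); bhi[3 * f + 2] = std::max({a.z, b.z, c.z});
  }
  NumericVector out(np);
  for (int i = 0; i < np; i++) {
    V3 p = row3(P, i);
    double best = R_PosInf;
    for (int f = 0; f < nf; f++) {
      // lower bound: squared distance to bbox
      double lb = 0;
      double pv[3] = {p.x, p.y, p.z};
      for (int d = 0; d < 3; d++) {
        double v = pv[d];
        if (v < blo[3 * f + d]) { double t = blo[3 * f + d] - v; lb += t * t; }
        else if (v > bhi[3 * f + d]) { double t = v - bhi[3 * f + d]; lb += t * t; }
      }
      if (lb >= best) continue;
      double d2 = point_tri_dist2(p, row3(V, F(f, 0)), row3(V, F(f, 1)), row3(V, F(f, 2)));
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// ---------------------------------------------------------------------------
// consistent face orientation via BFS over shared edges
// returns faces with consistent winding per connected component
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cs_orient_faces(int nverts, IntegerMatrix F) {
  int nf = F.nrow();
  IntegerMatrix out = clone(F);
  // undirected edge -> faces
  std::unordered_map<uint64_t, std::vector<int>> edges;
  edges.reserve(nf * 2);
  auto ekey = [&](int u, int v) -> uint64_t {
    return (uint64_t)std::min(u, v) * (uint64_t)nverts + (uint64_t)std::max(u, v);
  };
  for (int f = 0; f < nf; f++)
    for (int e = 0; e < 3; e++)
      edges[ekey(F(f, e), F(f, (e + 1) % 3))].push_back(f);
  std::vector<char> visited(nf, 0), flipped(nf, 0);
  int nflip = 0;
  bool consistent = true;
  auto dir_edge_in = [&](int f, int u, int v) -> int {
    // returns +1 if directed edge (u,v) present in face f's current winding,
    // -1 if (v,u), 0 otherwise
    int a = out(f, 0), b = out(f, 1), c = out(f, 2);
    int fe[3][2] = {{a, b}, {b, c}, {c, a}};
    for (int e = 0; e < 3; e++) {
      if (fe[e][0] == u && fe[e][1] == v) return 1;
      if (fe[e][0] == v && fe[e][1] == u) return -1;
    }
    return 0;
  };
  for (int s = 0; s < nf; s++) {
    if (visited[s]) continue;
    std::queue<int> q;
    q.push(s); visited[s] = 1;
    while (!q.empty()) {
      int f = q.front(); q.pop();
      int a = out(f, 0), b = out(f, 1), c = out(f, 2);
      int fe[3][2] = {{a, b}, {b, c}, {c, a}};
      for (int e = 0; e < 3; e++) {
        int u = fe[e][0], v = fe[e][1];
        auto &vec = edges[ekey(u, v)];
        if (vec.size() > 2) { consistent = false; continue; }
        for (int g : vec) {
          if (g == f || visited[g]) continue;
          int d = dir_edge_in(g, u, v);
          if (d == 1) { // same direction: neighbour must be flipped
            std::swap(out(g, 1), out(g, 2));
            flipped[g] = 1; nflip++;
          }
          visited[g] = 1;
          q.push(g);
        }
      }
    }
  }
  return List::create(_["faces"] = out, _["n_flipped"] = nflip, _["manifold"] = consistent);
}

// [[Rcpp::export]]
List cs_edge_stats(int nverts, IntegerMatrix F) {
  int nf = F.nrow();
  std::unordered_map<uint64_t, int> cnt;
  cnt.reserve(nf * 2);
  for (int f = 0; f < nf; f++)
    for (int e = 0; e < 3; e++) {
      int u = F(f, e), v = F(f, (e + 1) % 3);
      uint64_t key = (uint64_t)std::min(u, v) * (uint64_t)nverts + (uint64_t)std::max(u, v);
      cnt[key]++;
    }
  int nb = 0, nnm = 0;
  for (auto &kv : cnt) {
    if (kv.second == 1) nb++;
    else if (kv.second > 2) nnm++;
  }
  return List::create(_["n_edges"] = (int)cnt.size(),
                      _["n_boundary_edges"] = nb,
                      _["n_nonmanifold_edges"] = nnm);
}
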