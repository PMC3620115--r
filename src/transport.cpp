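// Photon-packet Monte Carlo engine: triangle-mesh ray tracing (with an AABB
// BVH for large meshes), per-photon counter-based RNG streams, and the
// step / absorb / scatter / boundary / roulette loop, with CW and
// time-gated recording and fluorescence excitation->emission conversion.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

static const double C_MM_PER_PS = 0.299792458;  // speed of light in vacuum
static const double EPS_HIT = 1e-7;             // discard hits closer than this (mm)
static const double INF_D = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// RNG: splitmix64 streams, one per photon index, keyed by the run seed so
// results are independent of execution order.
// ---------------------------------------------------------------------------
struct RNG {
  uint64_t s;
  static uint64_t fmix(uint64_t z) {
    z += 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  RNG(uint64_t seed, uint64_t stream) {
    s = fmix(seed ^ (0x9E3779B97F4A7C15ULL * (stream + 1)));
    s = fmix(s);
  }
  uint64_t next_u64() {
    s += 0x9E3779B97F4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform double on the open interval (0, 1)
  double u01() {
    return (static_cast<double>(next_u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// ---------------------------------------------------------------------------
// Vec3 helpers
// ---------------------------------------------------------------------------
struct V3 { double x, y, z; };
static inline V3 v3(double x, double y, double z) { V3 v; v.x = x; v.y = y; v.z = z; return v; }
static inline V3 add(V3 a, V3 b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 sub(V3 a, V3 b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 scl(V3 a, double k) { return v3(a.x * k, a.y * k, a.z * k); }
static inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(V3 a, V3 b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm3(V3 a) { return std::sqrt(dot(a, a)); }
static inline V3 unit(V3 a) { double n = norm3(a); return v3(a.x / n, a.y / n, a.z / n); }

// ---------------------------------------------------------------------------
// Triangle scene + BVH
// ---------------------------------------------------------------------------
struct Tri { V3 a, e1, e2; V3 n; int in_region, out_region; };

struct BVHNode {
  double lo[3], hi[3];
  int left, right;   // child node indices, -1 for leaf
  int start, count;  // triangle index range for leaves
};

struct TriScene {
  std::vector<Tri> tris;
  std::vector<BVHNode> nodes;
  std::vector<int> order;       // triangle ids in BVH leaf order
  bool use_bvh;
  int n_regions;

  void build_bvh(int leaf_size = 8) {
    size_t nt = tris.size();
    order.resize(nt);
    for (size_t i = 0; i < nt; ++i) order[i] = static_cast<int>(i);
    use_bvh = nt > 1000;
    if (!use_bvh) return;
    std::vector<V3> cent(nt);
    for (size_t i = 0; i < nt; ++i) {
      const Tri& t = tris[i];
      V3 b = add(t.a, add(t.e1, t.a)); // placeholder, replaced below
      (void)b;
      V3 p1 = add(t.a, t.e1), p2 = add(t.a, t.e2);
      cent[i] = scl(add(t.a, add(p1, p2)), 1.0 / 3.0);
    }
    nodes.clear();
    nodes.reserve(2 * nt / leaf_size + 4);
    build_node(0, static_cast<int>(nt), leaf_size, cent);
  }

  int build_node(int start, int count, int leaf_size, const std::vector<V3>& cent) {
    BVHNode nd;
    for (int k = 0; k < 3; ++k) { nd.lo[k] = INF_D; nd.hi[k] = -INF_D; }
    for (int i = start; i < start + count; ++i) {
      const Tri& t = tris[order[i]];
      V3 p[3] = { t.a, add(t.a, t.e1), add(t.a, t.e2) };
      for (int j = 0; j < 3; ++j) {
        double c[3] = { p[j].x, p[j].y, p[j].z };
        for (int k = 0; k < 3; ++k) {
          if (c[k] < nd.lo[k]) nd.lo[k] = c[k];
          if (c[k] > nd.hi[k]) nd.hi[k] = c[k];
        }
      }
    }
    int idx = static_cast<int>(nodes.size());
    nodes.push_back(nd);
    if (count <= leaf_size) {
      // keep leaf triangles sorted by id so ties resolve to the smallest id
      std::sort(order.begin() + start, order.begin() + start + count);
      nodes[idx].left = nodes[idx].right = -1;
      nodes[idx].start = start; nodes[idx].count = count;
      return idx;
    }
    int axis = 0;
    double ext[3] = { nd.hi[0] - nd.lo[0], nd.hi[1] - nd.lo[1], nd.hi[2] - nd.lo[2] };
    if (ext[1] > ext[axis]) axis = 1;
    if (ext[2] > ext[axis]) axis = 2;
    int mid = start + count / 2;
    std::nth_element(order.begin() + start, order.begin() + mid,
                     order.begin() + start + count,
                     [&](int a, int b) {
                       double ca = axis == 0 ? cent[a].x : (axis == 1 ? cent[a].y : cent[a].z);
                       double cb = axis == 0 ? cent[b].x : (axis == 1 ? cent[b].y : cent[b].z);
                       if (ca != cb) return ca < cb;
                       return a < b;
                     });
    nodes[idx].start = -1; nodes[idx].count = 0;
    int l = build_node(start, mid - start, leaf_size, cent);
    int r = build_node(mid, start + count - mid, leaf_size, cent);
    nodes[idx].left = l; nodes[idx].right = r;
    return idx;
  }
};

// Moller-Trumbore with inclusive edges; returns hit distance or -1.
static inline double tri_hit(const Tri& t, V3 o, V3 d, double tmin, double tmax) {
  V3 p = cross(d, t.e2);
  double det = dot(t.e1, p);
  if (std::fabs(det) < 1e-14) return -1.0;
  double inv = 1.0 / det;
  V3 s = sub(o, t.a);
  double u = dot(s, p) * inv;
  if (u < -1e-12 || u > 1.0 + 1e-12) return -1.0;
  V3 q = cross(s, t.e1);
  double v = dot(d, q) * inv;
  if (v < -1e-12 || u + v > 1.0 + 1e-12) return -1.0;
  double tt = dot(t.e2, q) * inv;
  if (tt <= tmin || tt > tmax) return -1.0;
  return tt;
}

static inline bool box_hit(const BVHNode& nd, V3 o, V3 inv_d, double tmax, double& tenter) {
  double t0 = 0.0, t1 = tmax;
  const double* lo = nd.lo; const double* hi = nd.hi;
  double oc[3] = { o.x, o.y, o.z };
  double id[3] = { inv_d.x, inv_d.y, inv_d.z };
  for (int k = 0; k < 3; ++k) {
    double ta = (lo[k] - oc[k]) * id[k];
    double tb = (hi[k] - oc[k]) * id[k];
    if (ta > tb) std::swap(ta, tb);
    if (ta > t0) t0 = ta;
    if (tb < t1) t1 = tb;
    if (t0 > t1) return false;
  }
  tenter = t0;
  return true;
}

// First hit along o + t*d, tmin < t <= tmax; ties broken by smallest tri id.
static bool first_hit(const TriScene& sc, V3 o, V3 d, double tmin, double tmax,
                      double& best_t, int& best_id) {
  best_t = INF_D; best_id = -1;
  if (!sc.use_bvh) {
    for (size_t i = 0; i < sc.tris.size(); ++i) {
      double tt = tri_hit(sc.tris[i], o, d, tmin, tmax);
      if (tt > 0 && (tt < best_t || (tt == best_t && static_cast<int>(i) < best_id)))
        { best_t = tt; best_id = static_cast<int>(i); }
    }
    return best_id >= 0;
  }
  V3 inv_d = v3(1.0 / d.x, 1.0 / d.y, 1.0 / d.z);
  int stack[128]; int sp = 0; stack[sp++] = 0;
  while (sp > 0) {
    const BVHNode& nd = sc.nodes[stack[--sp]];
    double tenter;
    double cap = (best_id >= 0) ? best_t : tmax;
    if (!box_hit(nd, o, inv_d, cap, tenter)) continue;
    if (nd.left < 0) {
      for (int i = nd.start; i < nd.start + nd.count; ++i) {
        int id = sc.order[i];
        double tt = tri_hit(sc.tris[id], o, d, tmin, tmax);
        if (tt > 0 && (tt < best_t || (tt == best_t && id < best_id)))
          { best_t = tt; best_id = id; }
      }
    } else {
      if (sp < 126) { stack[sp++] = nd.left; stack[sp++] = nd.right; }
    }
  }
  return best_id >= 0;
}

// ---------------------------------------------------------------------------
// Scene construction from R
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
SEXP cpp_scene_build(NumericMatrix V, IntegerMatrix F, NumericMatrix N,
                     IntegerVector tri_in, IntegerVector tri_out, int n_regions) {
  TriScene* sc = new TriScene();
  int nt = F.nrow();
  sc->tris.resize(nt);
  for (int i = 0; i < nt; ++i) {
    V3 a = v3(V(F(i, 0), 0), V(F(i, 0), 1), V(F(i, 0), 2));
    V3 b = v3(V(F(i, 1), 0), V(F(i, 1), 1), V(F(i, 1), 2));
    V3 c = v3(V(F(i, 2), 0), V(F(i, 2), 1), V(F(i, 2), 2));
    Tri& t = sc->tris[i];
    t.a = a; t.e1 = sub(b, a); t.e2 = sub(c, a);
    t.n = v3(N(i, 0), N(i, 1), N(i, 2));
    t.in_region = tri_in[i];
    t.out_region = tri_out[i];
  }
  sc->n_regions = n_regions;
  sc->build_bvh();
  XPtr<TriScene> ptr(sc, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_first_hits(SEXP scene_ptr, NumericMatrix O, NumericMatrix D,
                    NumericVector tmax, double tmin) {
  XPtr<TriScene> sc(scene_ptr);
  int n = O.nrow();
  NumericVector tt(n);
  IntegerVector id(n);
  for (int i = 0; i < n; ++i) {
    V3 o = v3(O(i, 0), O(i, 1), O(i, 2));
    V3 d = v3(D(i, 0), D(i, 1), D(i, 2));
    double bt; int bi;
    double cap = tmax[i % tmax.size()];
    if (first_hit(*sc, o, d, tmin, cap, bt, bi)) { tt[i] = bt; id[i] = bi + 1; }
    else { tt[i] = NA_REAL; id[i] = NA_INTEGER; }
  }
  return List::create(_["distance"] = tt, _["triangle"] = id);
}

// Brute-force reference scan (used as the test oracle against the BVH path).
// [[Rcpp::export]]
List cpp_first_hits_brute(SEXP scene_ptr, NumericMatrix O, NumericMatrix D,
                          NumericVector tmax, double tmin) {
  XPtr<TriScene> sc(scene_ptr);
  int n = O.nrow();
  NumericVector tt(n);
  IntegerVector id(n);
  for (int i = 0; i < n; ++i) {
    V3 o = v3(O(i, 0), O(i, 1), O(i, 2));
    V3 d = v3(D(i, 0), D(i, 1), D(i, 2));
    double bt = INF_D; int bi = -1;
    double cap = tmax[i % tmax.size()];
    for (size_t k = 0; k < sc->tris.size(); ++k) {
      double h = tri_hit(sc->tris[k], o, d, tmin, cap);
      if (h > 0 && (h < bt || (h == bt && static_cast<int>(k) < bi)))
        { bt = h; bi = static_cast<int>(k); }
    }
    if (bi >= 0) { tt[i] = bt; id[i] = bi + 1; } else { tt[i] = NA_REAL; id[i] = NA_INTEGER; }
  }
  return List::create(_["distance"] = tt, _["triangle"] = id);
}

// Count boundary crossings per region along a probe ray from each point.
// [[Rcpp::export]]
IntegerMatrix cpp_region_crossings(SEXP scene_ptr, NumericMatrix P, NumericVector dir) {
  XPtr<TriScene> sc(scene_ptr);
  int n = P.nrow();
  IntegerMatrix cnt(n, sc->n_regions);
  V3 d = unit(v3(dir[0], dir[1], dir[2]));
  for (int i = 0; i < n; ++i) {
    V3 o = v3(P(i, 0), P(i, 1), P(i, 2));
    for (size_t k = 0; k < sc->tris.size(); ++k) {
      double h = tri_hit(sc->tris[k], o, d, 1e-12, INF_D);
      if (h > 0) cnt(i, sc->tris[k].in_region - 1) += 1;
    }
  }
  return cnt;
}

// Is the open segment a->b blocked by any scene triangle?
// [[Rcpp::export]]
LogicalVector cpp_segment_blocked(SEXP scene_ptr, NumericMatrix A, NumericMatrix B,
                                  double eps) {
  XPtr<TriScene> sc(scene_ptr);
  int n = A.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    V3 a = v3(A(i, 0), A(i, 1), A(i, 2));
    V3 b = v3(B(i % B.nrow(), 0), B(i % B.nrow(), 1), B(i % B.nrow(), 2));
    V3 d = sub(b, a);
    double len = norm3(d);
    d = scl(d, 1.0 / len);
    double bt; int bi;
    out[i] = first_hit(*sc, a, d, eps, len - eps, bt, bi);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Physics helpers shared by the engine
// ---------------------------------------------------------------------------
static inline double hg_cos(double g, double xi) {
  if (std::fabs(g) < 1e-12) return 2.0 * xi - 1.0;
  double t = (1.0 - g * g) / (1.0 + g - 2.0 * g * xi);
  double c = (1.0 + g * g - t * t) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

static inline V3 rotate_dir(V3 u, double cost, double phi) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double cosp = std::cos(phi), sinp = std::sin(phi);
  if (std::fabs(u.z) > 0.99999) {
    // degenerate frame when travelling along +-z
    return v3(sint * cosp, sint * sinp, cost * (u.z > 0 ? 1.0 : -1.0));
  }
  double den = std::sqrt(1.0 - u.z * u.z);
  double nx = sint * (u.x * u.z * cosp - u.y * sinp) / den + u.x * cost;
  double ny = sint * (u.y * u.z * cosp + u.x * sinp) / den + u.y * cost;
  double nz = -sint * cosp * den + u.z * cost;
  V3 r = v3(nx, ny, nz);
  return unit(r);
}

// Unpolarized Fresnel reflectance for incidence cosine ci in [0,1].
static inline double fresnel_R(double ni, double nt, double ci) {
  if (ni == nt) return 0.0;
  if (ci > 1.0) ci = 1.0;
  if (ci < 0.0) ci = 0.0;
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double st = ni / nt * si;
  if (st >= 1.0) return 1.0;                    // total internal reflection
  double ct = std::sqrt(1.0 - st * st);
  if (ci > 0.999999999) {                       // normal-incidence limit
    double r = (ni - nt) / (ni + nt);
    return r * r;
  }
  double rs = (ni * ci - nt * ct) / (ni * ci + nt * ct);
  double rp = (nt * ci - ni * ct) / (nt * ci + ni * ct);
  return 0.5 * (rs * rs + rp * rp);
}

static inline V3 isotropic_dir(RNG& rng) {
  double cost = 2.0 * rng.u01() - 1.0;
  double phi = 2.0 * M_PI * rng.u01();
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  return v3(sint * std::cos(phi), sint * std::sin(phi), cost);
}

// ---------------------------------------------------------------------------
// Recorders
// ---------------------------------------------------------------------------
struct Recorders {
  // per-triangle exit weight, one slab per band
  std::vector<double> tri_exit[2];
  // cube face grids (CW): rows x cols x 6, band-major
  bool face_on;
  double face_cx, face_cy, face_cz, face_side;
  int face_rows, face_cols;
  std::vector<double> face[2];
  // absorption voxel grid
  bool abs_on;
  double ao[3], aspac;
  int adim[3];
  std::vector<double> absg[2];
  double abs_over[2];
  // time gates
  bool td_on;
  double t0, dt; int ngates;             // +1 overflow gate
  std::vector<double> exit_time[2];      // length ngates+1
  std::vector<double> abs_time[2];
  std::vector<double> tri_gate[2];       // nt x (ngates+1), col-major
  // exit log
  int log_cap, log_n;
  std::vector<double> log_rows;          // 10 columns

  int gate_of(double t) const {
    if (!td_on) return 0;
    double g = std::floor((t - t0) / dt);
    if (g < 0) return ngates;            // before first gate -> overflow too
    if (g >= ngates) return ngates;
    return static_cast<int>(g);
  }
};

// face index 0..5 = x-,x+,y-,y+,z-,z+ from the dominant axis of the exit
// point relative to the cube center.
static inline int cube_face_of(const Recorders& R, V3 p, int& row, int& col) {
  double l[3] = { p.x - R.face_cx, p.y - R.face_cy, p.z - R.face_cz };
  double h = R.face_side / 2.0;
  int ax = 0;
  double best = -1.0;
  for (int k = 0; k < 3; ++k) {
    double d = std::fabs(std::fabs(l[k]) - h);
    if (best < 0 || d < best) { best = d; ax = k; }
  }
  int face = ax * 2 + (l[ax] > 0 ? 1 : 0);
  int sp[2], si = 0;
  for (int k = 0; k < 3; ++k) if (k != ax) sp[si++] = k;   // ascending axes
  double u = l[sp[0]] + h, v = l[sp[1]] + h;               // from minimal corner
  double du = R.face_side / R.face_rows, dv = R.face_side / R.face_cols;
  row = static_cast<int>(std::floor(u / du));
  col = static_cast<int>(std::floor(v / dv));
  if (row >= R.face_rows) row = R.face_rows - 1;
  if (col >= R.face_cols) col = R.face_cols - 1;
  if (row < 0) row = 0;
  if (col < 0) col = 0;
  return face;
}

struct Totals {
  double launched, specular, missed;
  double deposited[2], exited[2], roulette_net[2], cap_lost[2];
  double converted_w;
  double n_exit[2];
  double n_roulette, n_converted, n_cap, n_missed;
};

// innermost region containing a point (0 = ambient), by crossing parity
static int locate_point(const TriScene& sc, V3 p, const std::vector<int>& depth) {
  V3 d = unit(v3(0.2672612419124244, 0.5345224838248488, 0.8017837257372732));
  std::vector<int> cnt(sc.n_regions, 0);
  for (size_t k = 0; k < sc.tris.size(); ++k) {
    double h = tri_hit(sc.tris[k], p, d, 1e-12, INF_D);
    if (h > 0) cnt[sc.tris[k].in_region - 1] += 1;
  }
  int best = 0, bestd = 0;
  for (int r = 0; r < sc.n_regions; ++r) {
    if (cnt[r] % 2 == 1 && depth[r] > bestd) { best = r + 1; bestd = depth[r]; }
  }
  return best;
}

// ---------------------------------------------------------------------------
// The engine
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_transport(SEXP scene_ptr, List props, List source, List fluoro,
                       List controls, List recorders) {
  XPtr<TriScene> scp(scene_ptr);
  TriScene& sc = *scp;
  int nt = static_cast<int>(sc.tris.size());
  int nreg = sc.n_regions;

  // optical property tables, index 0 = ambient
  NumericVector mua[2], mus[2], gg[2], nn[2];
  List pb0 = props["excitation"];
  mua[0] = pb0["mu_a"]; mus[0] = pb0["mu_s"]; gg[0] = pb0["g"]; nn[0] = pb0["n"];
  bool has_em = props.containsElementNamed("emission") &&
    !Rf_isNull(props["emission"]);
  if (has_em) {
    List pb1 = props["emission"];
    mua[1] = pb1["mu_a"]; mus[1] = pb1["mu_s"]; gg[1] = pb1["g"]; nn[1] = pb1["n"];
  }

  std::vector<int> depth = as<std::vector<int>>(props["region_depth"]);

  // fluorophore
  bool fl_on = fluoro.containsElementNamed("region") && !Rf_isNull(fluoro["region"]);
  int fl_region = fl_on ? as<int>(fluoro["region"]) : -1;
  double eta = fl_on ? as<double>(fluoro["eta"]) : 0.0;

  // controls
  double n_photons_d = as<double>(controls["n_photons"]);
  long long n_photons = static_cast<long long>(n_photons_d);
  uint64_t seed = static_cast<uint64_t>(as<double>(controls["seed"]));
  double total_power = as<double>(controls["total_power"]);
  double thr_frac = as<double>(controls["roulette_threshold"]);
  double m_roul = as<double>(controls["roulette_m"]);
  long long max_steps = static_cast<long long>(as<double>(controls["max_steps"]));

  // source
  std::string stype = as<std::string>(source["kind"]);
  NumericVector spos, sdir;
  double srad = 0.0;
  int sregion = 0;
  NumericVector sbb_lo, sbb_hi;
  NumericMatrix init;
  if (stype == "point" || stype == "sphere" || stype == "beam") {
    spos = source["position"];
  }
  if (stype == "sphere") srad = as<double>(source["radius"]);
  if (stype == "beam") sdir = source["direction"];
  if (stype == "region") {
    sregion = as<int>(source["region"]);
    sbb_lo = source["bbox_lo"]; sbb_hi = source["bbox_hi"];
  }
  if (stype == "init") {
    init = as<NumericMatrix>(source["states"]);
    n_photons = init.nrow();
  }
  double w0 = (stype == "init") ? NA_REAL : total_power / static_cast<double>(n_photons);
  double thr_abs = 0.0; // set per photon from its initial weight

  // recorders
  Recorders R;
  R.tri_exit[0].assign(nt, 0.0);
  R.tri_exit[1].assign(has_em ? nt : 0, 0.0);
  List fg = recorders["face_grid"];
  R.face_on = as<bool>(fg["enabled"]);
  if (R.face_on) {
    NumericVector c = fg["center"];
    R.face_cx = c[0]; R.face_cy = c[1]; R.face_cz = c[2];
    R.face_side = as<double>(fg["side"]);
    R.face_rows = as<int>(fg["rows"]); R.face_cols = as<int>(fg["cols"]);
    R.face[0].assign(static_cast<size_t>(R.face_rows) * R.face_cols * 6, 0.0);
    if (has_em) R.face[1].assign(static_cast<size_t>(R.face_rows) * R.face_cols * 6, 0.0);
  }
  List ab = recorders["absorption"];
  R.abs_on = as<bool>(ab["enabled"]);
  R.abs_over[0] = R.abs_over[1] = 0.0;
  if (R.abs_on) {
    NumericVector o = ab["origin"]; IntegerVector dm = ab["dims"];
    R.ao[0] = o[0]; R.ao[1] = o[1]; R.ao[2] = o[2];
    R.aspac = as<double>(ab["spacing"]);
    R.adim[0] = dm[0]; R.adim[1] = dm[1]; R.adim[2] = dm[2];
    size_t nv = static_cast<size_t>(R.adim[0]) * R.adim[1] * R.adim[2];
    R.absg[0].assign(nv, 0.0);
    if (has_em) R.absg[1].assign(nv, 0.0);
  }
  List td = recorders["gates"];
  R.td_on = as<bool>(td["enabled"]);
  if (R.td_on) {
    R.t0 = as<double>(td["start"]); R.dt = as<double>(td["dt"]);
    R.ngates = as<int>(td["n"]);
    for (int b = 0; b < (has_em ? 2 : 1); ++b) {
      R.exit_time[b].assign(R.ngates + 1, 0.0);
      R.abs_time[b].assign(R.ngates + 1, 0.0);
      R.tri_gate[b].assign(static_cast<size_t>(nt) * (R.ngates + 1), 0.0);
    }
  }
  R.log_cap = as<int>(recorders["exit_log_cap"]);
  R.log_n = 0;

  Totals T = {};
  long long warn_cap = 0;

  for (long long ip = 0; ip < n_photons; ++ip) {
    RNG rng(seed, static_cast<uint64_t>(ip));
    V3 pos, dir;
    double w, t = 0.0;
    int band = 0, region = 0;

    // --- launch ------------------------------------------------------------
    if (stype == "init") {
      pos = v3(init(ip, 0), init(ip, 1), init(ip, 2));
      dir = unit(v3(init(ip, 3), init(ip, 4), init(ip, 5)));
      w = init(ip, 6); t = init(ip, 7);
      region = locate_point(sc, pos, depth);
      T.launched += w;
    } else if (stype == "point") {
      pos = v3(spos[0], spos[1], spos[2]);
      dir = isotropic_dir(rng);
      w = w0;
      region = locate_point(sc, pos, depth);
      T.launched += w;
    } else if (stype == "sphere") {
      V3 c = v3(spos[0], spos[1], spos[2]);
      do {
        pos = v3(c.x + srad * (2.0 * rng.u01() - 1.0),
                 c.y + srad * (2.0 * rng.u01() - 1.0),
                 c.z + srad * (2.0 * rng.u01() - 1.0));
      } while (norm3(sub(pos, c)) > srad);
      dir = isotropic_dir(rng);
      w = w0;
      region = locate_point(sc, pos, depth);
      T.launched += w;
    } else if (stype == "region") {
      int tries = 0;
      do {
        pos = v3(sbb_lo[0] + rng.u01() * (sbb_hi[0] - sbb_lo[0]),
                 sbb_lo[1] + rng.u01() * (sbb_hi[1] - sbb_lo[1]),
                 sbb_lo[2] + rng.u01() * (sbb_hi[2] - sbb_lo[2]));
        region = locate_point(sc, pos, depth);
        if (++tries > 100000) stop("source region rejection sampling failed");
      } while (region != sregion);
      dir = isotropic_dir(rng);
      w = w0;
      T.launched += w;
    } else { // beam: external, enters through the surface with a specular loss
      pos = v3(spos[0], spos[1], spos[2]);
      dir = unit(v3(sdir[0], sdir[1], sdir[2]));
      w = w0;
      T.launched += w;
      double bt; int bi;
      if (!first_hit(sc, pos, dir, EPS_HIT, INF_D, bt, bi)) {
        T.missed += w; T.n_missed += 1; continue;
      }
      const Tri& tr = sc.tris[bi];
      bool entering = dot(dir, tr.n) < 0;
      int other = entering ? tr.in_region : tr.out_region;
      V3 nf = entering ? tr.n : scl(tr.n, -1.0);
      double ci = -dot(dir, nf);
      double ni = nn[0][region], ntr = nn[0][other];
      double Rs = fresnel_R(ni, ntr, ci);
      T.specular += w * Rs;
      w *= (1.0 - Rs);
      // refract
      if (ni != ntr) {
        double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
        double st = ni / ntr * si;
        double ct = std::sqrt(std::max(0.0, 1.0 - st * st));
        dir = unit(add(scl(dir, ni / ntr), scl(nf, ni / ntr * ci - ct)));
      }
      // move to the entry point, then nudge inside along the refracted
      // direction; the clock starts at tissue entry
      V3 entry = add(v3(spos[0], spos[1], spos[2]),
                     scl(unit(v3(sdir[0], sdir[1], sdir[2])), bt));
      pos = add(entry, scl(dir, EPS_HIT));
      region = other;
    }
    thr_abs = thr_frac * ((stype == "init") ? w : w0);

    // --- propagate ---------------------------------------------------------
    double su = -std::log(rng.u01());
    long long steps = 0;
    while (true) {
      if (++steps > max_steps) { T.cap_lost[band] += w; T.n_cap += 1; ++warn_cap; break; }
      double ma = mua[band][region], ms = mus[band][region];
      double mut = ma + ms;
      double s = (mut > 0.0) ? su / mut : INF_D;
      double bt; int bi;
      bool hit = first_hit(sc, pos, dir, EPS_HIT, s, bt, bi);
      if (hit) {
        t += bt * nn[band][region] / C_MM_PER_PS;
        pos = add(pos, scl(dir, bt));
        if (mut > 0.0) { su -= bt * mut; if (su < 0) su = 0; }
        const Tri& tr = sc.tris[bi];
        bool entering = dot(dir, tr.n) < 0;
        int other = entering ? tr.in_region : tr.out_region;
        V3 nf = entering ? tr.n : scl(tr.n, -1.0);
        double ci = -dot(dir, nf);
        double ni = nn[band][region], ntr = nn[band][other];
        double Rr = fresnel_R(ni, ntr, ci);
        if (rng.u01() <= Rr) {
          dir = unit(sub(dir, scl(nf, 2.0 * dot(dir, nf))));   // reflect
        } else {
          if (ni != ntr) {
            double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
            double st = ni / ntr * si;
            double ct = std::sqrt(std::max(0.0, 1.0 - st * st));
            dir = unit(add(scl(dir, ni / ntr), scl(nf, ni / ntr * ci - ct)));
          }
          region = other;
          if (region == 0) {
            // exit through the outermost boundary: record residual weight
            T.exited[band] += w; T.n_exit[band] += 1;
            R.tri_exit[band][bi] += w;
            if (R.face_on && band < (has_em ? 2 : 1)) {
              int row, col;
              int face = cube_face_of(R, pos, row, col);
              R.face[band][static_cast<size_t>(face) * R.face_rows * R.face_cols +
                           static_cast<size_t>(col) * R.face_rows + row] += w;
            }
            if (R.td_on) {
              int gidx = R.gate_of(t);
              R.exit_time[band][gidx] += w;
              R.tri_gate[band][static_cast<size_t>(gidx) * nt + bi] += w;
            }
            if (R.log_cap > 0 && R.log_n < R.log_cap) {
              double rowv[10] = { pos.x, pos.y, pos.z, dir.x, dir.y, dir.z,
                                  w, t, static_cast<double>(bi + 1),
                                  static_cast<double>(band) };
              R.log_rows.insert(R.log_rows.end(), rowv, rowv + 10);
              R.log_n += 1;
            }
            break;
          }
        }
        pos = add(pos, scl(dir, EPS_HIT));  // nudge off the surface
        continue;
      }
      // interaction site
      if (!std::isfinite(s)) { T.cap_lost[band] += w; T.n_cap += 1; break; }
      t += s * nn[band][region] / C_MM_PER_PS;
      pos = add(pos, scl(dir, s));
      double dw = (ma > 0.0) ? w * ma / mut : 0.0;
      if (dw > 0.0) {
        w -= dw;
        T.deposited[band] += dw;
        if (R.abs_on) {
          int ix = static_cast<int>(std::floor((pos.x - R.ao[0]) / R.aspac));
          int iy = static_cast<int>(std::floor((pos.y - R.ao[1]) / R.aspac));
          int iz = static_cast<int>(std::floor((pos.z - R.ao[2]) / R.aspac));
          if (ix >= 0 && iy >= 0 && iz >= 0 &&
              ix < R.adim[0] && iy < R.adim[1] && iz < R.adim[2]) {
            R.absg[band][static_cast<size_t>(iz) * R.adim[0] * R.adim[1] +
                         static_cast<size_t>(iy) * R.adim[0] + ix] += dw;
          } else {
            R.abs_over[band] += dw;
          }
        }
        if (R.td_on) R.abs_time[band][R.gate_of(t)] += dw;
      }
      // fluorescence conversion (excitation band only, inside the fluorophore)
      if (fl_on && band == 0 && region == fl_region && has_em) {
        if (rng.u01() < eta) {
          T.converted_w += w; T.n_converted += 1;
          band = 1;
          dir = isotropic_dir(rng);
          su = -std::log(rng.u01());
          continue;
        }
      }
      // scatter
      double cost = hg_cos(gg[band][region], rng.u01());
      double phi = 2.0 * M_PI * rng.u01();
      dir = rotate_dir(dir, cost, phi);
      // roulette
      if (thr_abs > 0.0 && w < thr_abs) {
        if (rng.u01() <= 1.0 / m_roul) {
          T.roulette_net[band] -= (m_roul - 1.0) * w;
          w *= m_roul;
        } else {
          T.roulette_net[band] += w; T.n_roulette += 1;
          break;
        }
      }
      if (w <= 0.0) break;   // fully absorbed (non-scattering medium)
      su = -std::log(rng.u01());
    }
  }

  if (warn_cap > 0)
    Rf_warning("%lld photon(s) hit the step-count cap; their weight was logged to a diagnostics bucket", warn_cap);

  int nb = has_em ? 2 : 1;
  List out;
  List tri_exit(nb), face(nb), absg(nb), exit_time(nb), abs_time(nb), tri_gate(nb);
  CharacterVector bnames = has_em ? CharacterVector::create("excitation", "emission")
                                  : CharacterVector::create("excitation");
  for (int b = 0; b < nb; ++b) {
    tri_exit[b] = NumericVector(R.tri_exit[b].begin(), R.tri_exit[b].end());
    if (R.face_on) {
      NumericVector f(R.face[b].begin(), R.face[b].end());
      f.attr("dim") = IntegerVector::create(R.face_rows, R.face_cols, 6);
      face[b] = f;
    }
    if (R.abs_on) {
      NumericVector a(R.absg[b].begin(), R.absg[b].end());
      a.attr("dim") = IntegerVector::create(R.adim[0], R.adim[1], R.adim[2]);
      absg[b] = a;
    }
    if (R.td_on) {
      exit_time[b] = NumericVector(R.exit_time[b].begin(), R.exit_time[b].end());
      abs_time[b] = NumericVector(R.abs_time[b].begin(), R.abs_time[b].end());
      NumericVector tg(R.tri_gate[b].begin(), R.tri_gate[b].end());
      tg.attr("dim") = IntegerVector::create(nt, R.ngates + 1);
      tri_gate[b] = tg;
    }
  }
  tri_exit.attr("names") = bnames;
  if (R.face_on) face.attr("names") = bnames;
  if (R.abs_on) absg.attr("names") = bnames;
  if (R.td_on) {
    exit_time.attr("names") = bnames;
    abs_time.attr("names") = bnames;
    tri_gate.attr("names") = bnames;
  }
  NumericMatrix logm(R.log_n, 10);
  for (int i = 0; i < R.log_n; ++i)
    for (int j = 0; j < 10; ++j) logm(i, j) = R.log_rows[static_cast<size_t>(i) * 10 + j];

  List totals = List::create(
    _["launched"] = T.launched,
    _["specular"] = T.specular,
    _["missed"] = T.missed,
    _["deposited"] = NumericVector::create(T.deposited[0], T.deposited[1]),
    _["exited"] = NumericVector::create(T.exited[0], T.exited[1]),
    _["roulette_net"] = NumericVector::create(T.roulette_net[0], T.roulette_net[1]),
    _["cap_lost"] = NumericVector::create(T.cap_lost[0], T.cap_lost[1]),
    _["converted_weight"] = T.converted_w,
    _["absorption_overflow"] = NumericVector::create(R.abs_over[0], R.abs_over[1]),
    _["n_exited"] = NumericVector::create(T.n_exit[0], T.n_exit[1]),
    _["n_roulette_killed"] = T.n_roulette,
    _["n_converted"] = T.n_converted,
    _["n_step_cap"] = T.n_cap,
    _["n_missed"] = T.n_missed);

  return List::create(
    _["tri_exit"] = tri_exit,
    _["face_grid"] = R.face_on ? face : List(0),
    _["absorption"] = R.abs_on ? absg : List(0),
    _["exit_time"] = R.td_on ? exit_time : List(0),
    _["absorbed_time"] = R.td_on ? abs_time : List(0),
    _["tri_gate"] = R.td_on ? tri_gate : List(0),
    _["exit_log"] = logm,
    _["totals"] = totals);
}

// [[Rcpp::export]]
bool cpp_scene_uses_bvh(SEXP scene_ptr) {
  XPtr<TriScene> sc(scene_ptr);
  return sc->use_bvh;
}
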