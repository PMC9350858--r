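// Core engine: SDF evaluation, scene queries, boundary optics, the
// sphere-tracing transport loop, voxel path-length deposition and sources.
// All lengths are in cm; the coordinate frame is right-handed.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <limits>
#include <vector>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------- vectors

struct Vec3 {
  double x, y, z;
};
static inline Vec3 v3(double x, double y, double z) { return {x, y, z}; }
static inline Vec3 operator+(Vec3 a, Vec3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
static inline Vec3 operator-(Vec3 a, Vec3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline Vec3 operator*(double s, Vec3 a) { return {s * a.x, s * a.y, s * a.z}; }
static inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline double norm(Vec3 a) { return std::sqrt(dot(a, a)); }
static inline Vec3 normalize(Vec3 a) {
  double n = norm(a);
  return {a.x / n, a.y / n, a.z / n};
}
static inline bool finite3(Vec3 a) {
  return std::isfinite(a.x) && std::isfinite(a.y) && std::isfinite(a.z);
}

static Vec3 asVec3(const NumericVector& v) {
  if (v.size() != 3) stop("expected a length-3 numeric vector");
  return {v[0], v[1], v[2]};
}
static NumericVector fromVec3(Vec3 a) { return NumericVector::create(a.x, a.y, a.z); }

// ---------------------------------------------------------------- RNG
// splitmix64: small, fast, passes BigCrush; one independent stream per
// photon packet keyed on (seed, packet index) so runs are reproducible
// regardless of the order packets are processed in.

struct RNG {
  uint64_t s;
  uint64_t next() {
    s += 0x9E3779B97F4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform on (0, 1]: excludes 0 so -log(u) is finite
  double u01() { return double((next() >> 11) + 1) * (1.0 / 9007199254740992.0); }
  // uniform on [0, 1)
  double u0() { return double(next() >> 11) * (1.0 / 9007199254740992.0); }
};

static uint64_t mix64(uint64_t z) {
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static RNG photon_rng(uint64_t seed, uint64_t i) {
  RNG r;
  r.s = mix64(seed ^ 0x5851F42D4C957F2DULL) ^ mix64((i + 1) * 0xD1B54A32D192ED03ULL);
  return r;
}

// ---------------------------------------------------------------- SDF nodes
// Node trees are flattened into a vector; children referenced by index.

enum NodeKind {
  K_SPHERE = 0,
  K_BOX = 1,
  K_CAPSULE = 2,
  K_CYLINDER = 3,
  K_UNION = 10,
  K_SMOOTH_UNION = 11,
  K_INTERSECTION = 12,
  K_SUBTRACTION = 13,
  K_TRANSFORM = 20
};

struct Node {
  int kind;
  double p[7];    // leaf parameters / smoothing k
  double rot[9];  // transform: local -> world rotation (row major)
  double trn[3];  // transform: translation
  int c1, c2;     // child indices (-1 if none)
};

static int build_node(const List& spec, std::vector<Node>& out);

static int push_children(const List& spec, std::vector<Node>& out, Node& nd) {
  List ch = spec["children"];
  if (ch.size() != 2) stop("CSG node needs exactly 2 children");
  nd.c1 = build_node(ch[0], out);
  nd.c2 = build_node(ch[1], out);
  return 0;
}

static int build_node(const List& spec, std::vector<Node>& out) {
  std::string kind = as<std::string>(spec["kind"]);
  Node nd;
  nd.c1 = nd.c2 = -1;
  for (int i = 0; i < 7; ++i) nd.p[i] = 0.0;
  if (kind == "sphere") {
    nd.kind = K_SPHERE;
    nd.p[0] = as<double>(spec["r"]);
    if (!(nd.p[0] > 0)) stop("sphere radius must be > 0");
  } else if (kind == "box") {
    nd.kind = K_BOX;
    Vec3 he = asVec3(spec["half"]);
    if (!(he.x > 0 && he.y > 0 && he.z > 0)) stop("box half-extents must be > 0");
    nd.p[0] = he.x; nd.p[1] = he.y; nd.p[2] = he.z;
  } else if (kind == "capsule") {
    nd.kind = K_CAPSULE;
    Vec3 a = asVec3(spec["a"]), b = asVec3(spec["b"]);
    double r = as<double>(spec["r"]);
    if (!(r > 0)) stop("capsule radius must be > 0");
    if (!(norm(b - a) > 0)) stop("capsule segment is degenerate");
    nd.p[0] = a.x; nd.p[1] = a.y; nd.p[2] = a.z;
    nd.p[3] = b.x; nd.p[4] = b.y; nd.p[5] = b.z;
    nd.p[6] = r;
  } else if (kind == "cylinder") {
    nd.kind = K_CYLINDER;
    nd.p[0] = as<double>(spec["half_height"]);
    nd.p[1] = as<double>(spec["r"]);
    if (!(nd.p[0] > 0 && nd.p[1] > 0)) stop("cylinder parameters must be > 0");
  } else if (kind == "union") {
    nd.kind = K_UNION;
    push_children(spec, out, nd);
  } else if (kind == "smooth_union") {
    nd.kind = K_SMOOTH_UNION;
    nd.p[0] = as<double>(spec["k"]);
    if (!(nd.p[0] > 0)) stop("smooth_union blend radius k must be > 0");
    push_children(spec, out, nd);
  } else if (kind == "intersection") {
    nd.kind = K_INTERSECTION;
    push_children(spec, out, nd);
  } else if (kind == "subtraction") {
    nd.kind = K_SUBTRACTION;
    push_children(spec, out, nd);
  } else if (kind == "transform") {
    nd.kind = K_TRANSFORM;
    NumericMatrix R = spec["rotation"];
    if (R.nrow() != 3 || R.ncol() != 3) stop("rotation must be 3x3");
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) nd.rot[3 * i + j] = R(i, j);
    Vec3 t = asVec3(spec["translation"]);
    nd.trn[0] = t.x; nd.trn[1] = t.y; nd.trn[2] = t.z;
    List ch = spec["children"];
    if (ch.size() != 1) stop("transform node needs exactly 1 child");
    nd.c1 = build_node(ch[0], out);
  } else {
    stop("unknown SDF node kind: '%s'", kind.c_str());
  }
  out.push_back(nd);
  return (int)out.size() - 1;
}

static double eval_node(const std::vector<Node>& ns, int idx, Vec3 p) {
  const Node& nd = ns[idx];
  switch (nd.kind) {
    case K_SPHERE:
      return norm(p) - nd.p[0];
    case K_BOX: {
      double qx = std::fabs(p.x) - nd.p[0];
      double qy = std::fabs(p.y) - nd.p[1];
      double qz = std::fabs(p.z) - nd.p[2];
      double ox = std::max(qx, 0.0), oy = std::max(qy, 0.0), oz = std::max(qz, 0.0);
      double outside = std::sqrt(ox * ox + oy * oy + oz * oz);
      double inside = std::min(std::max(qx, std::max(qy, qz)), 0.0);
      return outside + inside;
    }
    case K_CAPSULE: {
      Vec3 a = v3(nd.p[0], nd.p[1], nd.p[2]);
      Vec3 ab = v3(nd.p[3], nd.p[4], nd.p[5]) - a;
      Vec3 pa = p - a;
      double h = dot(pa, ab) / dot(ab, ab);
      h = std::min(std::max(h, 0.0), 1.0);
      return norm(pa - h * ab) - nd.p[6];
    }
    case K_CYLINDER: {
      double dr = std::hypot(p.x, p.y) - nd.p[1];
      double dz = std::fabs(p.z) - nd.p[0];
      double inside = std::min(std::max(dr, dz), 0.0);
      double ox = std::max(dr, 0.0), oz = std::max(dz, 0.0);
      return inside + std::hypot(ox, oz);
    }
    case K_UNION:
      return std::min(eval_node(ns, nd.c1, p), eval_node(ns, nd.c2, p));
    case K_SMOOTH_UNION: {
      double d1 = eval_node(ns, nd.c1, p), d2 = eval_node(ns, nd.c2, p);
      double k = nd.p[0];
      double h = std::max(k - std::fabs(d1 - d2), 0.0) / k;
      return std::min(d1, d2) - h * h * k * 0.25;
    }
    case K_INTERSECTION:
      return std::max(eval_node(ns, nd.c1, p), eval_node(ns, nd.c2, p));
    case K_SUBTRACTION:
      return std::max(eval_node(ns, nd.c1, p), -eval_node(ns, nd.c2, p));
    case K_TRANSFORM: {
      // stored rotation maps local -> world; evaluate child at R^T (p - t)
      double dx = p.x - nd.trn[0], dy = p.y - nd.trn[1], dz = p.z - nd.trn[2];
      Vec3 q = v3(nd.rot[0] * dx + nd.rot[3] * dy + nd.rot[6] * dz,
                  nd.rot[1] * dx + nd.rot[4] * dy + nd.rot[7] * dz,
                  nd.rot[2] * dx + nd.rot[5] * dy + nd.rot[8] * dz);
      return eval_node(ns, nd.c1, q);
    }
  }
  return NA_REAL;  // unreachable
}

static Vec3 normal_node(const std::vector<Node>& ns, int idx, Vec3 p, double h) {
  Vec3 g = v3(
      eval_node(ns, idx, p + v3(h, 0, 0)) - eval_node(ns, idx, p - v3(h, 0, 0)),
      eval_node(ns, idx, p + v3(0, h, 0)) - eval_node(ns, idx, p - v3(0, h, 0)),
      eval_node(ns, idx, p + v3(0, 0, h)) - eval_node(ns, idx, p - v3(0, 0, h)));
  return g;  // unnormalised gradient * 2h; caller normalises / checks degeneracy
}

// ---------------------------------------------------------------- media & scene

struct Medium {
  double mus, mua, g, n;
  double mut() const { return mus + mua; }
  double albedo() const {
    double t = mut();
    return t > 0 ? mus / t : 0.0;
  }
};

static Medium parse_medium(const List& m) {
  Medium md;
  md.mus = as<double>(m["mu_s"]);
  md.mua = as<double>(m["mu_a"]);
  md.g = as<double>(m["g"]);
  md.n = as<double>(m["n"]);
  if (md.mus < 0 || md.mua < 0) stop("mu_s and mu_a must be >= 0");
  if (!(std::fabs(md.g) < 1)) stop("anisotropy g must lie in (-1, 1)");
  if (md.n < 1) stop("refractive index must be >= 1");
  return md;
}

struct SceneC {
  std::vector<Node> nodes;
  std::vector<int> root_idx;    // node index per region
  std::vector<Medium> media;    // per region
  std::vector<int> layer;       // per region
  Vec3 bbox_center, bbox_half;
  Medium ambient;
  double delta_s;
  double normal_h;
  long step_cap;

  double bbox_signed(Vec3 p) const {
    double qx = std::fabs(p.x - bbox_center.x) - bbox_half.x;
    double qy = std::fabs(p.y - bbox_center.y) - bbox_half.y;
    double qz = std::fabs(p.z - bbox_center.z) - bbox_half.z;
    double ox = std::max(qx, 0.0), oy = std::max(qy, 0.0), oz = std::max(qz, 0.0);
    return std::sqrt(ox * ox + oy * oy + oz * oz) +
           std::min(std::max(qx, std::max(qy, qz)), 0.0);
  }

  // nearest surface among regions only (as exposed to R); -1 when no region
  double nearest_region(Vec3 p, int& which) const {
    double dmin = INF;
    which = -1;
    for (size_t i = 0; i < root_idx.size(); ++i) {
      double d = std::fabs(eval_node(nodes, root_idx[i], p));
      if (d < dmin) { dmin = d; which = (int)i; }
    }
    return dmin;
  }

  // region index at p (-1 = ambient); highest layer wins, then declaration order
  int region_at(Vec3 p) const {
    int best = -1;
    int best_layer = 0;
    for (size_t i = 0; i < root_idx.size(); ++i) {
      if (eval_node(nodes, root_idx[i], p) < 0) {
        if (best == -1 || layer[i] > best_layer) { best = (int)i; best_layer = layer[i]; }
      }
    }
    return best;
  }

  const Medium& medium_of(int region) const {
    return region < 0 ? ambient : media[region];
  }
};

static SceneC parse_scene(const List& sc) {
  SceneC s;
  List regions = sc["regions"];
  for (int i = 0; i < regions.size(); ++i) {
    List reg = regions[i];
    s.root_idx.push_back(build_node(reg["node"], s.nodes));
    s.media.push_back(parse_medium(reg["medium"]));
    s.layer.push_back(as<int>(reg["layer"]));
  }
  List bb = sc["bbox"];
  s.bbox_center = asVec3(bb["center"]);
  s.bbox_half = asVec3(bb["half"]);
  if (!(s.bbox_half.x > 0 && s.bbox_half.y > 0 && s.bbox_half.z > 0))
    stop("bbox half-extents must be > 0");
  s.ambient = parse_medium(sc["ambient"]);
  s.delta_s = as<double>(sc["delta_s"]);
  if (!(s.delta_s > 0)) stop("delta_s must be > 0");
  s.normal_h = as<double>(sc["normal_h"]);
  s.step_cap = (long)as<double>(sc["step_cap"]);
  return s;
}

// ---------------------------------------------------------------- optics

static double fresnel_R(double n1, double n2, double cosi) {
  double s2 = (n1 / n2) * (n1 / n2) * (1.0 - cosi * cosi);
  if (s2 >= 1.0) return 1.0;  // total internal reflection
  double cost = std::sqrt(1.0 - s2);
  double rs = (n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost);
  double rp = (n1 * cost - n2 * cosi) / (n1 * cost + n2 * cosi);
  return 0.5 * (rs * rs + rp * rp);
}

static Vec3 reflect_dir(Vec3 d, Vec3 n) { return d - (2.0 * dot(d, n)) * n; }

// n oriented against incidence (dot(d, n) < 0); returns false on TIR
static bool refract_dir(Vec3 d, Vec3 n, double n1, double n2, Vec3& out) {
  double eta = n1 / n2;
  double cosi = -dot(d, n);
  double k = 1.0 - eta * eta * (1.0 - cosi * cosi);
  if (k < 0.0) return false;
  out = normalize(eta * d + (eta * cosi - std::sqrt(k)) * n);
  return true;
}

static double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-6) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - f * f) / (2.0 * g);
  return std::min(1.0, std::max(-1.0, c));
}

// rotate direction by polar angle with cosine ct and azimuth phi (MCML frame)
static Vec3 scatter_dir(Vec3 d, double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(d.z) > 0.99999) {
    return v3(st * cp, st * sp, ct * (d.z >= 0 ? 1.0 : -1.0));
  }
  double tmp = std::sqrt(1.0 - d.z * d.z);
  Vec3 nd = v3(st * (d.x * d.z * cp - d.y * sp) / tmp + d.x * ct,
               st * (d.y * d.z * cp + d.x * sp) / tmp + d.y * ct,
               -st * cp * tmp + d.z * ct);
  return normalize(nd);
}

// ---------------------------------------------------------------- fluence grid

struct GridC {
  int nx, ny, nz;
  Vec3 origin, spacing;
  double* acc;  // column-major [nx, ny, nz]

  double lo(int i) const { return i == 0 ? origin.x : (i == 1 ? origin.y : origin.z); }
  double sp(int i) const { return i == 0 ? spacing.x : (i == 1 ? spacing.y : spacing.z); }
  int dim(int i) const { return i == 0 ? nx : (i == 1 ? ny : nz); }
};

// 3D DDA: split segment a->b at voxel faces, crediting each voxel with
// weight * (sub-segment length). Segments outside the grid are clipped.
static void deposit_seg(GridC& G, Vec3 a, Vec3 b, double w) {
  Vec3 dv = b - a;
  double L = norm(dv);
  if (!(L > 0)) return;
  Vec3 u = v3(dv.x / L, dv.y / L, dv.z / L);
  double uu[3] = {u.x, u.y, u.z};
  double aa[3] = {a.x, a.y, a.z};
  double t0 = 0.0, t1 = L;
  for (int i = 0; i < 3; ++i) {
    double lo = G.lo(i), hi = lo + G.dim(i) * G.sp(i);
    if (std::fabs(uu[i]) < 1e-300) {
      if (aa[i] < lo || aa[i] > hi) return;
    } else {
      double ta = (lo - aa[i]) / uu[i], tb = (hi - aa[i]) / uu[i];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta);
      t1 = std::min(t1, tb);
    }
  }
  if (!(t1 > t0)) return;
  double pp[3] = {a.x + t0 * u.x, a.y + t0 * u.y, a.z + t0 * u.z};
  int ix[3], stp[3], dims[3] = {G.nx, G.ny, G.nz};
  double tMax[3], tDel[3];
  for (int i = 0; i < 3; ++i) {
    double rel = (pp[i] - G.lo(i)) / G.sp(i);
    ix[i] = (int)std::floor(rel);
    if (ix[i] < 0) ix[i] = 0;
    if (ix[i] >= dims[i]) ix[i] = dims[i] - 1;  // max-edge points: last voxel
    if (uu[i] > 1e-300) {
      stp[i] = 1;
      tMax[i] = t0 + (G.lo(i) + (ix[i] + 1) * G.sp(i) - pp[i]) / uu[i];
      tDel[i] = G.sp(i) / uu[i];
    } else if (uu[i] < -1e-300) {
      stp[i] = -1;
      tMax[i] = t0 + (G.lo(i) + ix[i] * G.sp(i) - pp[i]) / uu[i];
      tDel[i] = -G.sp(i) / uu[i];
    } else {
      stp[i] = 0;
      tMax[i] = INF;
      tDel[i] = INF;
    }
  }
  double tcur = t0;
  for (;;) {
    int ax = 0;
    if (tMax[1] < tMax[ax]) ax = 1;
    if (tMax[2] < tMax[ax]) ax = 2;
    double tnext = tMax[ax];
    double tend = std::min(tnext, t1);
    if (tend > tcur)
      G.acc[ix[0] + (size_t)G.nx * (ix[1] + (size_t)G.ny * ix[2])] += w * (tend - tcur);
    if (tnext >= t1) break;
    tcur = tnext;
    ix[ax] += stp[ax];
    if (ix[ax] < 0 || ix[ax] >= dims[ax]) break;
    tMax[ax] += tDel[ax];
  }
}

static GridC parse_grid(const List& g, std::vector<double>& store, bool allocate) {
  GridC G;
  IntegerVector dims = g["dims"];
  if (dims.size() != 3) stop("grid dims must have length 3");
  G.nx = dims[0]; G.ny = dims[1]; G.nz = dims[2];
  if (G.nx < 1 || G.ny < 1 || G.nz < 1) stop("grid dims must be >= 1");
  G.origin = asVec3(g["origin"]);
  G.spacing = asVec3(g["spacing"]);
  if (!(G.spacing.x > 0 && G.spacing.y > 0 && G.spacing.z > 0))
    stop("grid spacing must be > 0");
  if (allocate) {
    store.assign((size_t)G.nx * G.ny * G.nz, 0.0);
    G.acc = store.data();
  }
  return G;
}

// ---------------------------------------------------------------- sources

struct SourceC {
  int kind;  // 0 isotropic point, 1 rectangle with fixed direction
  Vec3 origin;
  double hx, hy;   // rectangle half-extents along uax / vax
  Vec3 uax, vax;   // in-plane axes of the emitting rectangle
  Vec3 dir;
};

static SourceC parse_source(const List& s) {
  SourceC src;
  std::string kind = as<std::string>(s["kind"]);
  src.origin = asVec3(s["origin"]);
  if (kind == "isotropic_point") {
    src.kind = 0;
    src.hx = src.hy = 0;
    src.uax = v3(1, 0, 0); src.vax = v3(0, 1, 0);
    src.dir = v3(0, 0, -1);
  } else if (kind == "rectangle") {
    src.kind = 1;
    NumericVector h = s["half"];
    if (h.size() != 2) stop("rectangle source half must have length 2");
    src.hx = h[0]; src.hy = h[1];
    if (src.hx < 0 || src.hy < 0) stop("rectangle half-extents must be >= 0");
    src.uax = normalize(asVec3(s["u_axis"]));
    src.vax = normalize(asVec3(s["v_axis"]));
    src.dir = normalize(asVec3(s["direction"]));
  } else {
    stop("unknown source kind: '%s'", kind.c_str());
  }
  return src;
}

static void emit_one(const SourceC& s, RNG& r, Vec3& pos, Vec3& dir) {
  if (s.kind == 0) {
    pos = s.origin;
    double cz = 2.0 * r.u0() - 1.0;
    double phi = 2.0 * M_PI * r.u0();
    double st = std::sqrt(std::max(0.0, 1.0 - cz * cz));
    dir = v3(st * std::cos(phi), st * std::sin(phi), cz);
  } else {
    pos = s.origin + ((2.0 * r.u0() - 1.0) * s.hx) * s.uax +
          ((2.0 * r.u0() - 1.0) * s.hy) * s.vax;
    dir = s.dir;
  }
}

// ---------------------------------------------------------------- transport

struct Tally {
  long n_absorbed = 0, n_escaped = 0, n_capped = 0, n_degenerate = 0;
};

struct TraceRec {
  std::vector<int> event;     // see codes in R docs
  std::vector<double> px, py, pz;
  std::vector<int> region;
  bool active = false;
  void log(int ev, Vec3 p, int reg) {
    if (!active) return;
    event.push_back(ev);
    px.push_back(p.x); py.push_back(p.y); pz.push_back(p.z);
    region.push_back(reg + 1);  // 1-based; 0 = ambient
  }
};

// event codes
enum {
  EV_LAUNCH = 0, EV_MARCH = 1, EV_SCATTER = 2, EV_ABSORB = 3,
  EV_PASS = 4, EV_REFLECT = 5, EV_REFRACT = 6, EV_ESCAPE = 7,
  EV_CAP = 8, EV_DEGENERATE = 9
};

// Propagate one packet to its terminal event. Returns terminal code
// (EV_ABSORB / EV_ESCAPE / EV_CAP / EV_DEGENERATE) and the scatter count.
static int propagate_one(const SceneC& S, GridC* G, RNG& rng, Vec3 pos, Vec3 dir,
                         int& nsc, Vec3& exit_pos, Vec3& exit_dir, TraceRec& tr) {
  int reg = S.region_at(pos);
  Medium med = S.medium_of(reg);
  double tau = -std::log(rng.u01());
  nsc = 0;
  tr.log(EV_LAUNCH, pos, reg);
  for (long step = 0; step < S.step_cap; ++step) {
    if (!finite3(pos) || !finite3(dir))
      stop("non-finite photon state at step %ld (pos %g %g %g)", step, pos.x, pos.y, pos.z);
    double db = S.bbox_signed(pos);
    if (db > 0) {
      exit_pos = pos; exit_dir = dir;
      tr.log(EV_ESCAPE, pos, reg);
      return EV_ESCAPE;
    }
    // nearest surface over regions and the bounding box; marching uses |D|
    int near_reg;
    double dsdf = S.nearest_region(pos, near_reg);
    double dbb = std::fabs(db);
    bool near_is_bbox = dbb < dsdf;
    if (near_is_bbox) dsdf = dbb;

    if (dsdf < S.delta_s) {
      double nudge = 2.0 * S.delta_s;
      if (near_is_bbox) {  // bbox is an absorbing frontier, not an interface
        Vec3 np = pos + nudge * dir;
        if (G) deposit_seg(*G, pos, np, 1.0);
        pos = np;
        tr.log(EV_PASS, pos, reg);
        reg = S.region_at(pos);
        med = S.medium_of(reg);
        continue;
      }
      // Incident-side index from the packet's tracked medium, far side from
      // a probe ahead. (Probing behind instead would mis-assign n1 when a
      // freshly refracted grazing ray re-triggers the boundary band and
      // bounce it back through the interface it just crossed.)
      int r_out = S.region_at(pos + nudge * dir);
      double n1 = med.n, n2 = S.medium_of(r_out).n;
      if (n1 == n2) {  // index-matched: slide through, switch properties
        Vec3 np = pos + nudge * dir;
        if (G) deposit_seg(*G, pos, np, 1.0);
        tau -= std::max(0.0, nudge * med.mut());
        if (tau < 0) tau = 0;
        pos = np;
        reg = S.region_at(pos);
        med = S.medium_of(reg);
        tr.log(EV_PASS, pos, reg);
        continue;
      }
      Vec3 gvec = normal_node(S.nodes, S.root_idx[near_reg], pos, S.normal_h);
      double gn = norm(gvec);
      if (!(gn > 0)) {
        tr.log(EV_DEGENERATE, pos, reg);
        exit_pos = pos; exit_dir = dir;
        return EV_DEGENERATE;
      }
      Vec3 nrm = v3(gvec.x / gn, gvec.y / gn, gvec.z / gn);
      if (dot(dir, nrm) > 0) nrm = -1.0 * nrm;  // orient against incidence
      double cosi = -dot(dir, nrm);
      if (cosi > 1.0) cosi = 1.0;
      double R = fresnel_R(n1, n2, cosi);
      bool reflected = rng.u0() < R;
      if (reflected) {
        dir = normalize(reflect_dir(dir, nrm));
      } else {
        Vec3 td;
        refract_dir(dir, nrm, n1, n2, td);  // R < 1 guarantees a real solution
        dir = td;
      }
      // Nudge along the surface normal, not the ray: a near-critical
      // refracted (or grazing reflected) ray is almost tangent, and a nudge
      // along it would not clear the detection band -- the packet would be
      // re-labelled on the wrong side and trapped in a spurious
      // whispering-gallery orbit.
      Vec3 np = pos + (reflected ? nudge : -nudge) * nrm;
      if (G) deposit_seg(*G, pos, np, 1.0);
      pos = np;
      reg = S.region_at(pos);
      med = S.medium_of(reg);
      tr.log(reflected ? EV_REFLECT : EV_REFRACT, pos, reg);
      continue;
    }

    double mut = med.mut();
    double dint = mut > 0 ? tau / mut : INF;
    if (dint <= dsdf) {  // interaction point reached (ties -> interaction)
      Vec3 np = pos + dint * dir;
      if (G) deposit_seg(*G, pos, np, 1.0);
      pos = np;
      if (rng.u0() < med.albedo()) {
        ++nsc;
        double ct = hg_cos(med.g, rng.u0());
        double phi = 2.0 * M_PI * rng.u0();
        dir = scatter_dir(dir, ct, phi);
        tau = -std::log(rng.u01());
        tr.log(EV_SCATTER, pos, reg);
      } else {
        tr.log(EV_ABSORB, pos, reg);
        exit_pos = pos; exit_dir = dir;
        return EV_ABSORB;
      }
    } else {  // march the sphere-tracing step
      Vec3 np = pos + dsdf * dir;
      if (G) deposit_seg(*G, pos, np, 1.0);
      pos = np;
      if (mut > 0) tau -= dsdf * mut;
      tr.log(EV_MARCH, pos, reg);
    }
  }
  exit_pos = pos; exit_dir = dir;
  tr.log(EV_CAP, pos, reg);
  return EV_CAP;
}

// ---------------------------------------------------------------- exports

// [[Rcpp::export]]
NumericVector cpp_sdf_eval(List node, NumericMatrix pts) {
  std::vector<Node> ns;
  int root = build_node(node, ns);
  int n = pts.nrow();
  if (pts.ncol() != 3) stop("points must be an n x 3 matrix");
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = eval_node(ns, root, v3(pts(i, 0), pts(i, 1), pts(i, 2)));
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sdf_normal(List node, NumericVector p, double h) {
  if (!(h > 0)) stop("finite-difference step h must be > 0");
  std::vector<Node> ns;
  int root = build_node(node, ns);
  Vec3 g = normal_node(ns, root, asVec3(p), h);
  double gn = norm(g);
  if (!(gn > 0)) stop("degenerate surface normal: zero SDF gradient (medial axis?)");
  return fromVec3(v3(g.x / gn, g.y / gn, g.z / gn));
}

// [[Rcpp::export]]
List cpp_scene_distance(List scene, NumericVector p) {
  SceneC S = parse_scene(scene);
  if (S.root_idx.empty()) stop("scene has no regions");
  int which;
  double d = S.nearest_region(asVec3(p), which);
  return List::create(_["distance"] = d, _["region"] = which + 1);
}

// [[Rcpp::export]]
int cpp_region_at(List scene, NumericVector p) {
  SceneC S = parse_scene(scene);
  Vec3 q = asVec3(p);
  if (S.bbox_signed(q) > 0) stop("point lies outside the scene bounding box");
  return S.region_at(q) + 1;  // 0 = ambient
}

// [[Rcpp::export]]
IntegerVector cpp_rasterize(List scene, IntegerVector dims, NumericVector origin,
                            NumericVector spacing) {
  SceneC S = parse_scene(scene);
  if (dims.size() != 3) stop("dims must have length 3");
  Vec3 o = asVec3(origin), sp = asVec3(spacing);
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out((size_t)nx * ny * nz);
  size_t k = 0;
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        // column-major order matches R array layout after dim<- assignment
        Vec3 c = v3(o.x + (ix + 0.5) * sp.x, o.y + (iy + 0.5) * sp.y,
                    o.z + (iz + 0.5) * sp.z);
        out[ix + (size_t)nx * (iy + (size_t)ny * iz)] = S.region_at(c) + 1;
        ++k;
      }
  (void)k;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_hg_cosine(double g, NumericVector u) {
  if (!(std::fabs(g) < 1)) stop("anisotropy g must lie in (-1, 1)");
  NumericVector out(u.size());
  for (int i = 0; i < u.size(); ++i) out[i] = hg_cos(g, u[i]);
  return out;
}

// [[Rcpp::export]]
double cpp_fresnel(double n1, double n2, double cos_i) {
  if (n1 < 1 || n2 < 1) stop("refractive indices must be >= 1");
  if (!(cos_i > 0 && cos_i <= 1))
    stop("cos_i must lie in (0, 1]; check surface-normal orientation");
  return fresnel_R(n1, n2, cos_i);
}

// [[Rcpp::export]]
NumericVector cpp_reflect(NumericVector d, NumericVector n) {
  return fromVec3(normalize(reflect_dir(normalize(asVec3(d)), normalize(asVec3(n)))));
}

// [[Rcpp::export]]
List cpp_refract(NumericVector d, NumericVector n, double n1, double n2) {
  Vec3 out;
  bool ok = refract_dir(normalize(asVec3(d)), normalize(asVec3(n)), n1, n2, out);
  return List::create(_["direction"] = ok ? fromVec3(out) : NumericVector(0),
                      _["tir"] = !ok);
}

// [[Rcpp::export]]
List cpp_emit(List source, int n, double seed) {
  SourceC src = parse_source(source);
  NumericMatrix pos(n, 3), dir(n, 3);
  for (int i = 0; i < n; ++i) {
    RNG r = photon_rng((uint64_t)seed, (uint64_t)i);
    Vec3 p, d;
    emit_one(src, r, p, d);
    pos(i, 0) = p.x; pos(i, 1) = p.y; pos(i, 2) = p.z;
    dir(i, 0) = d.x; dir(i, 1) = d.y; dir(i, 2) = d.z;
  }
  return List::create(_["position"] = pos, _["direction"] = dir);
}

// [[Rcpp::export]]
NumericVector cpp_deposit_path(IntegerVector dims, NumericVector origin,
                               NumericVector spacing, NumericVector accum,
                               NumericVector p0, NumericVector p1, double weight) {
  std::vector<double> dummy;
  List g = List::create(_["dims"] = dims, _["origin"] = origin, _["spacing"] = spacing);
  GridC G = parse_grid(g, dummy, false);
  if (accum.size() != (R_xlen_t)((size_t)G.nx * G.ny * G.nz))
    stop("accumulator length does not match grid dims");
  NumericVector out = clone(accum);
  G.acc = REAL(out);
  deposit_seg(G, asVec3(p0), asVec3(p1), weight);
  return out;
}

// [[Rcpp::export]]
List cpp_run_mcrt(List scene, List source, int n_photons, double seed,
                  Nullable<List> grid, bool record_exits) {
  SceneC S = parse_scene(scene);
  SourceC src = parse_source(source);
  std::vector<double> store;
  GridC G;
  bool has_grid = grid.isNotNull();
  if (has_grid) G = parse_grid(grid.get(), store, true);
  IntegerVector nsc(n_photons), kind(n_photons);
  NumericMatrix epos(record_exits ? n_photons : 0, 3),
      edir(record_exits ? n_photons : 0, 3);
  Tally tally;
  TraceRec tr;  // inactive
  for (int i = 0; i < n_photons; ++i) {
    if (i % 8192 == 0) Rcpp::checkUserInterrupt();
    RNG r = photon_rng((uint64_t)seed, (uint64_t)i);
    Vec3 p, d, ep, ed;
    emit_one(src, r, p, d);
    int ns;
    int ev = propagate_one(S, has_grid ? &G : nullptr, r, p, d, ns, ep, ed, tr);
    nsc[i] = ns;
    kind[i] = ev;
    if (ev == EV_ABSORB) ++tally.n_absorbed;
    else if (ev == EV_ESCAPE) ++tally.n_escaped;
    else if (ev == EV_CAP) ++tally.n_capped;
    else ++tally.n_degenerate;
    if (record_exits) {
      epos(i, 0) = ep.x; epos(i, 1) = ep.y; epos(i, 2) = ep.z;
      edir(i, 0) = ed.x; edir(i, 1) = ed.y; edir(i, 2) = ed.z;
    }
  }
  List out = List::create(
      _["n_scatters"] = nsc, _["terminal"] = kind,
      _["n_absorbed"] = (double)tally.n_absorbed,
      _["n_escaped"] = (double)tally.n_escaped,
      _["n_capped"] = (double)tally.n_capped,
      _["n_degenerate"] = (double)tally.n_degenerate);
  if (has_grid) {
    NumericVector acc(store.begin(), store.end());
    out["accumulator"] = acc;
  }
  if (record_exits) {
    out["exit_position"] = epos;
    out["exit_direction"] = edir;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_propagate_trace(List scene, NumericVector position, NumericVector direction,
                         double seed, int substream, int burn) {
  SceneC S = parse_scene(scene);
  RNG r = photon_rng((uint64_t)seed, (uint64_t)substream);
  for (int i = 0; i < burn; ++i) r.u0();  // replay runs: sources draw first
  TraceRec tr;
  tr.active = true;
  Vec3 ep, ed;
  int ns;
  int ev = propagate_one(S, nullptr, r, asVec3(position), normalize(asVec3(direction)),
                         ns, ep, ed, tr);
  int m = (int)tr.event.size();
  IntegerVector evs(m), regs(m);
  NumericMatrix pts(m, 3);
  for (int i = 0; i < m; ++i) {
    evs[i] = tr.event[i];
    regs[i] = tr.region[i];
    pts(i, 0) = tr.px[i]; pts(i, 1) = tr.py[i]; pts(i, 2) = tr.pz[i];
  }
  return List::create(_["event"] = evs, _["position"] = pts, _["region"] = regs,
                      _["terminal"] = ev, _["n_scatters"] = ns,
                      _["exit_position"] = fromVec3(ep),
                      _["exit_direction"] = fromVec3(ed));
}
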