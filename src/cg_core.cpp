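// Core of the coarse-grained chromatin model: energy terms and the
// Metropolis Monte Carlo kernel. Energies are in kT at the reference
// temperature; replica temperatures are dimensionless multipliers.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------- vectors

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double a, double b, double c) : x(a), y(b), z(c) {}
};
static inline Vec3 operator+(const Vec3& a, const Vec3& b) { return Vec3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline Vec3 operator-(const Vec3& a, const Vec3& b) { return Vec3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline Vec3 operator*(double s, const Vec3& a) { return Vec3(s * a.x, s * a.y, s * a.z); }
static inline double dot(const Vec3& a, const Vec3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }
static inline Vec3 unit(const Vec3& a) { double n = norm(a); return (1.0 / n) * a; }

// rotate w about unit axis by angle (Rodrigues)
static inline Vec3 rotate_axis(const Vec3& w, const Vec3& axis, double ang) {
  double c = std::cos(ang), s = std::sin(ang);
  return c * w + s * cross(axis, w) + (dot(axis, w) * (1.0 - c)) * axis;
}

// minimal rotation taking unit vector a to unit vector b, applied to w
static inline Vec3 min_rotate(const Vec3& w, const Vec3& a, const Vec3& b) {
  Vec3 ax = cross(a, b);
  double s = norm(ax), c = dot(a, b);
  if (s < 1e-12) {
    if (c > 0) return w;                     // parallel
    // antiparallel: rotate by pi about any axis perpendicular to a
    Vec3 p = std::fabs(a.x) < 0.9 ? Vec3(1, 0, 0) : Vec3(0, 1, 0);
    Vec3 perp = unit(p - dot(p, a) * a);
    return rotate_axis(w, perp, M_PI);
  }
  Vec3 axn = (1.0 / s) * ax;
  double ang = std::atan2(s, c);
  return rotate_axis(w, axn, ang);
}

// minimum distance between segments p0-p1 and q0-q1 (Ericson, RTCD 5.1.9)
static double seg_seg_dist(const Vec3& p0, const Vec3& p1,
                           const Vec3& q0, const Vec3& q1) {
  Vec3 d1 = p1 - p0, d2 = q1 - q0, r = p0 - q0;
  double a = dot(d1, d1), e = dot(d2, d2), f = dot(d2, r);
  double s, t;
  const double EPS = 1e-12;
  if (a <= EPS && e <= EPS) return norm(r);
  if (a <= EPS) { s = 0.0; t = f / e; t = std::min(1.0, std::max(0.0, t)); }
  else {
    double c = dot(d1, r);
    if (e <= EPS) { t = 0.0; s = std::min(1.0, std::max(0.0, -c / a)); }
    else {
      double b = dot(d1, d2), denom = a * e - b * b;
      s = denom > EPS ? std::min(1.0, std::max(0.0, (b * f - c * e) / denom)) : 0.0;
      t = (b * s + f) / e;
      if (t < 0) { t = 0; s = std::min(1.0, std::max(0.0, -c / a)); }
      else if (t > 1) { t = 1; s = std::min(1.0, std::max(0.0, (b - c) / a)); }
    }
  }
  Vec3 c1 = p0 + s * d1, c2 = q0 + t * d2;
  return norm(c1 - c2);
}

static double point_seg_dist(const Vec3& p, const Vec3& a, const Vec3& b) {
  Vec3 ab = b - a;
  double t = dot(p - a, ab) / std::max(dot(ab, ab), 1e-12);
  t = std::min(1.0, std::max(0.0, t));
  Vec3 c = a + t * ab;
  return norm(p - c);
}

// ---------------------------------------------------------------- RNG
// xoshiro256** seeded via splitmix64: per-replica substreams independent of
// the R RNG.
struct RNG {
  uint64_t s[4];
  explicit RNG(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; i++) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) { return (v << k) | (v >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double runif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double runif(double a, double b) { return a + (b - a) * runif(); }
  int rint(int n) { return (int)(runif() * n) % n; }
  Vec3 rsphere() {
    double z = runif(-1.0, 1.0), phi = runif(0.0, 2.0 * M_PI);
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    return Vec3(r * std::cos(phi), r * std::sin(phi), z);
  }
};

// ---------------------------------------------------------------- model

struct Topo {
  int n_seg, n_joint, n_stem;
  std::vector<double> l0, ks;          // per segment
  std::vector<int> is_stem;            // per segment (0/1)
  std::vector<int> stem_seg;           // per stem, 0-based segment index
  std::vector<double> stem_d;
  std::vector<Vec3> stem_dvec;         // displacement direction in stem frame
  std::vector<double> stem_rrel;       // per stem, 9 (column-major 3x3)
  std::vector<double> theta0, kb, kt;  // per joint (size n_joint)
  std::vector<int> chg_seg;            // per charge point, 0-based segment
  std::vector<double> chg_frac, chg_q;
  std::vector<std::vector<int> > seg_chg;  // charge-point ids per segment
};

struct FF {
  double debye, lB, e_max, D, h, cutoff, taper_from, w;
  double r_dna, r_nuc, ev_k, ev_cap, es_cutoff;
  bool es_on, ev_on;
};

struct State {
  std::vector<Vec3> P;  // joints, n_joint
  std::vector<Vec3> V;  // frame v per segment, n_seg
};

static Topo parse_topo(const List& tl) {
  Topo T;
  T.n_seg = as<int>(tl["n_seg"]);
  T.n_joint = T.n_seg + 1;
  NumericVector l0 = tl["l0"], ks = tl["ks"], theta0 = tl["theta0"],
                kb = tl["kb"], kt = tl["kt"];
  IntegerVector is_stem = tl["is_stem"], stem_seg = tl["stem_seg"];
  T.l0.assign(l0.begin(), l0.end());
  T.ks.assign(ks.begin(), ks.end());
  T.theta0.assign(theta0.begin(), theta0.end());
  T.kb.assign(kb.begin(), kb.end());
  T.kt.assign(kt.begin(), kt.end());
  T.is_stem.assign(is_stem.begin(), is_stem.end());
  T.n_stem = stem_seg.size();
  T.stem_seg.resize(T.n_stem);
  for (int i = 0; i < T.n_stem; i++) T.stem_seg[i] = stem_seg[i] - 1;
  NumericVector sd = tl["stem_d"];
  T.stem_d.assign(sd.begin(), sd.end());
  NumericMatrix dv = tl["stem_dvec"];
  NumericMatrix rr = tl["stem_rrel"];
  T.stem_dvec.resize(T.n_stem);
  T.stem_rrel.resize(9 * T.n_stem);
  for (int i = 0; i < T.n_stem; i++) {
    T.stem_dvec[i] = Vec3(dv(i, 0), dv(i, 1), dv(i, 2));
    for (int k = 0; k < 9; k++) T.stem_rrel[9 * i + k] = rr(i, k);
  }
  IntegerVector cs = tl["chg_seg"];
  NumericVector cf = tl["chg_frac"], cq = tl["chg_q"];
  T.chg_frac.assign(cf.begin(), cf.end());
  T.chg_q.assign(cq.begin(), cq.end());
  T.chg_seg.resize(cs.size());
  T.seg_chg.assign(T.n_seg, std::vector<int>());
  for (int i = 0; i < cs.size(); i++) {
    T.chg_seg[i] = cs[i] - 1;
    T.seg_chg[T.chg_seg[i]].push_back(i);
  }
  return T;
}

static FF parse_ff(const List& fl) {
  FF f;
  f.debye = as<double>(fl["debye_length"]);
  f.lB = as<double>(fl["bjerrum_length"]);
  f.e_max = as<double>(fl["e_max"]);
  f.D = as<double>(fl["nucleosome_diameter"]);
  f.h = as<double>(fl["nucleosome_height"]);
  f.cutoff = as<double>(fl["cutoff"]);
  f.taper_from = as<double>(fl["taper_from"]);
  f.w = as<double>(fl["well_width"]);
  f.r_dna = as<double>(fl["ev_radius_dna"]);
  f.r_nuc = as<double>(fl["ev_radius_nuc"]);
  f.ev_k = as<double>(fl["ev_strength"]);
  f.ev_cap = as<double>(fl["ev_cap"]);
  f.es_cutoff = as<double>(fl["es_cutoff"]);
  f.es_on = as<bool>(fl["electrostatics"]);
  f.ev_on = as<bool>(fl["excluded_volume"]);
  return f;
}

static inline Vec3 seg_u(const State& S, int s) { return unit(S.P[s + 1] - S.P[s]); }

// nucleosome center and symmetry axis from the stem frame
static void stem_geom(const State& S, const Topo& T, int k, Vec3* center, Vec3* axis) {
  int s = T.stem_seg[k];
  Vec3 u = seg_u(S, s);
  Vec3 v = S.V[s];
  Vec3 f = cross(u, v);
  Vec3 mid = 0.5 * (S.P[s] + S.P[s + 1]);
  const Vec3& dv = T.stem_dvec[k];
  *center = mid + T.stem_d[k] * (dv.x * u + dv.y * v + dv.z * f);
  const double* R = &T.stem_rrel[9 * k];  // column-major; axis = 3rd column
  // nucleosome frame N = [u v f] * R; axis = N * e3
  double cx = R[6], cy = R[7], cz = R[8];
  *axis = cx * u + cy * v + cz * f;
}

// anisotropic contact distance: h face-to-face, D side-by-side
static inline double contact_sigma(const FF& ff, double A2, double B2) {
  return ff.h + (ff.D - ff.h) * (1.0 - 0.5 * (A2 + B2));
}

// internucleosomal pair potential: depth-normalized so the global minimum is
// exactly -e_max at coaxial face-to-face stacking; exactly 0 beyond cutoff
static double nuc_pair_energy(const Vec3& ci, const Vec3& ai,
                              const Vec3& cj, const Vec3& aj, const FF& ff) {
  Vec3 rv = cj - ci;
  double r = norm(rv);
  if (r >= ff.cutoff || ff.e_max <= 0) return 0.0;
  double rr = std::max(r, 1e-9);
  Vec3 rhat = (1.0 / rr) * rv;
  double A = dot(ai, rhat), B = dot(aj, rhat), C = dot(ai, aj);
  double A2 = A * A, B2 = B * B;
  // depth anisotropy: isotropic floor + stacking preference; equals 1 only
  // at coaxial face-to-face alignment so the global minimum is -e_max there
  double s = (A2 + B2 + C * C) / 3.0;
  double eps = (0.55 + 0.45 * s) * (0.55 + 0.45 * s);
  double sig = contact_sigma(ff, A2, B2);
  double denom = r - sig + ff.w;
  double x = denom < 0.25 * ff.w ? 4.0 : ff.w / denom;
  double x6 = x * x * x; x6 *= x6;
  double u = x6 * x6 - 2.0 * x6;
  double t = 1.0;
  if (r > ff.taper_from) {
    double s = (ff.cutoff - r) / (ff.cutoff - ff.taper_from);
    t = s * s * (3.0 - 2.0 * s);
  }
  double e = ff.e_max * eps * u * t;
  return e > ff.ev_cap ? ff.ev_cap : e;
}

static inline double quartic_overlap(double d, double contact, const FF& ff) {
  if (d >= contact) return 0.0;
  double del = 1.0 - d / contact;
  double e = ff.ev_k * del * del * del * del;
  return e > ff.ev_cap ? ff.ev_cap : e;
}

// segment status codes for incremental evaluation
enum { ST_STATIC = 0, ST_RIGID = 1, ST_DEFORMED = 2 };

static inline bool pair_needed(int a, int b) {
  if (a == ST_DEFORMED || b == ST_DEFORMED) return true;
  return (a == ST_RIGID) != (b == ST_RIGID);
}

// Pair-term caches rebuilt per evaluated state.
struct PairCache {
  std::vector<Vec3> mid;
  std::vector<Vec3> ncen, naxi;
  std::vector<int> stem_of;  // stem id per segment, -1 for linkers
  std::vector<Vec3> chg_pos;
};

static void build_cache(const State& S, const Topo& T, PairCache& C) {
  const int n = T.n_seg;
  C.mid.resize(n);
  for (int s = 0; s < n; s++) C.mid[s] = 0.5 * (S.P[s] + S.P[s + 1]);
  C.ncen.resize(T.n_stem); C.naxi.resize(T.n_stem);
  for (int k = 0; k < T.n_stem; k++) stem_geom(S, T, k, &C.ncen[k], &C.naxi[k]);
  C.stem_of.assign(n, -1);
  for (int k = 0; k < T.n_stem; k++) C.stem_of[T.stem_seg[k]] = k;
  C.chg_pos.resize(T.chg_seg.size());
  for (size_t a = 0; a < T.chg_seg.size(); a++) {
    int s = T.chg_seg[a];
    C.chg_pos[a] = S.P[s] + T.chg_frac[a] * (S.P[s + 1] - S.P[s]);
  }
}

// linker-linker terms (electrostatics + DNA-DNA excluded volume), i != j
static inline void linker_pair_terms(const State& S, const Topo& T,
                                     const FF& ff, const PairCache& C,
                                     int i, int j, double out[3]) {
  double dd_contact = 2.0 * ff.r_dna;
  double reach = 0.5 * (T.l0[i] + T.l0[j]) +
                 (ff.es_on ? ff.es_cutoff : dd_contact);
  Vec3 dm = C.mid[j] - C.mid[i];
  double dm2 = dot(dm, dm);
  if (dm2 > reach * reach) return;
  if (ff.ev_on) {
    double ev_reach = 0.5 * (T.l0[i] + T.l0[j]) + dd_contact;
    if (dm2 <= ev_reach * ev_reach) {
      double d = seg_seg_dist(S.P[i], S.P[i + 1], S.P[j], S.P[j + 1]);
      out[2] += quartic_overlap(d, dd_contact, ff);
    }
  }
  if (ff.es_on) {
    const std::vector<int>& ci = T.seg_chg[i];
    const std::vector<int>& cj = T.seg_chg[j];
    double cut2 = ff.es_cutoff * ff.es_cutoff;
    for (size_t a = 0; a < ci.size(); a++) {
      const Vec3& pa = C.chg_pos[ci[a]];
      double qa = T.chg_q[ci[a]];
      for (size_t b = 0; b < cj.size(); b++) {
        Vec3 dr = C.chg_pos[cj[b]] - pa;
        double r2 = dot(dr, dr);
        if (r2 < cut2) {
          double r = std::sqrt(r2);
          out[0] += ff.lB * qa * T.chg_q[cj[b]] *
                    std::exp(-r / ff.debye) / std::max(r, 1e-9);
        }
      }
    }
  }
}

// stem a vs stem b: anisotropic pair potential + excluded volume
static inline void stem_pair_terms(const Topo& T, const FF& ff,
                                   const PairCache& C, int a, int b,
                                   double out[3]) {
  out[1] += nuc_pair_energy(C.ncen[a], C.naxi[a], C.ncen[b], C.naxi[b], ff);
  if (ff.ev_on) {
    Vec3 rv = C.ncen[b] - C.ncen[a];
    double r = norm(rv);
    if (r < ff.D) {
      double rr = std::max(r, 1e-9);
      Vec3 rhat = (1.0 / rr) * rv;
      double A = dot(C.naxi[a], rhat), B = dot(C.naxi[b], rhat);
      double sig = contact_sigma(ff, A * A, B * B);
      out[2] += quartic_overlap(r, sig, ff);
    }
  }
}

// stem a vs linker segment j excluded volume
static inline void stem_linker_terms(const State& S, const Topo& T,
                                     const FF& ff, const PairCache& C,
                                     int a, int j, double out[3]) {
  if (!ff.ev_on) return;
  double dn_contact = ff.r_dna + ff.r_nuc;
  double reach = 0.5 * T.l0[j] + dn_contact + T.stem_d[a] + 1.0;
  Vec3 dm = C.mid[j] - C.ncen[a];
  if (dot(dm, dm) > reach * reach) return;
  double d = point_seg_dist(C.ncen[a], S.P[j], S.P[j + 1]);
  out[2] += quartic_overlap(d, dn_contact, ff);
}

// valid interacting pair of segments i != j (adjacency exclusions)
static inline bool seg_pair_valid(const Topo& T, int i, int j) {
  if (i == j) return false;
  bool si = T.is_stem[i], sj = T.is_stem[j];
  if (!si && !sj) return std::abs(i - j) > 1;
  if (si && sj) return true;
  return std::abs(i - j) > 2;  // stem vs linker
}

static inline void seg_pair_terms(const State& S, const Topo& T,
                                  const FF& ff, const PairCache& C,
                                  int i, int j, double out[3]) {
  bool si = T.is_stem[i], sj = T.is_stem[j];
  if (!si && !sj) linker_pair_terms(S, T, ff, C, i, j, out);
  else if (si && sj) {
    int a = C.stem_of[i], b = C.stem_of[j];
    stem_pair_terms(T, ff, C, a < b ? a : b, a < b ? b : a, out);
  } else if (si) stem_linker_terms(S, T, ff, C, C.stem_of[i], j, out);
  else stem_linker_terms(S, T, ff, C, C.stem_of[j], i, out);
}

// full es, nuc, ev sums
static void pair_sums_full(const State& S, const Topo& T, const FF& ff,
                           double out[3]) {
  out[0] = out[1] = out[2] = 0.0;
  PairCache C;
  build_cache(S, T, C);
  const int n = T.n_seg;
  for (int i = 0; i < n; i++)
    for (int j = i + 1; j < n; j++)
      if (seg_pair_valid(T, i, j)) seg_pair_terms(S, T, ff, C, i, j, out);
}

// partial sums over pairs whose energy can change: affected-vs-all, with
// rigid-rigid pairs skipped and affected-affected pairs counted once
static void pair_sums_partial(const State& S, const Topo& T, const FF& ff,
                              const std::vector<int>& affected,
                              const signed char* status, double out[3]) {
  out[0] = out[1] = out[2] = 0.0;
  PairCache C;
  build_cache(S, T, C);
  const int n = T.n_seg;
  for (size_t k = 0; k < affected.size(); k++) {
    int i = affected[k];
    for (int j = 0; j < n; j++) {
      if (!seg_pair_valid(T, i, j)) continue;
      if (status[j] != ST_STATIC) {       // both affected
        if (j < i) continue;              // count once
        if (!pair_needed(status[i], status[j])) continue;
      }
      seg_pair_terms(S, T, ff, C, i, j, out);
    }
  }
}

// bend + torsion at one interior joint j (between segments j-1 and j)
static void joint_energy(const State& S, const Topo& T, int j,
                         double* e_bend, double* e_tor) {
  Vec3 u0 = seg_u(S, j - 1), u1 = seg_u(S, j);
  double c = std::min(1.0, std::max(-1.0, dot(u0, u1)));
  double th = std::acos(c) - T.theta0[j];
  *e_bend += 0.5 * T.kb[j] * th * th;
  if (T.kt[j] > 0) {
    Vec3 vt = min_rotate(S.V[j - 1], u0, u1);
    double tw = std::atan2(dot(cross(vt, S.V[j]), u1), dot(vt, S.V[j]));
    *e_tor += 0.5 * T.kt[j] * tw * tw;
  }
}

// stretch, bend, torsion; status == NULL -> full
static void elastic_sums(const State& S, const Topo& T,
                         const signed char* status, double out[3]) {
  out[0] = out[1] = out[2] = 0.0;
  for (int s = 0; s < T.n_seg; s++) {
    if (status && status[s] == ST_STATIC) continue;
    double dl = norm(S.P[s + 1] - S.P[s]) - T.l0[s];
    out[0] += 0.5 * T.ks[s] * dl * dl;
  }
  for (int j = 1; j < T.n_seg; j++) {
    if (status && status[j - 1] == ST_STATIC && status[j] == ST_STATIC)
      continue;
    joint_energy(S, T, j, &out[1], &out[2]);
  }
}

static void full_energy(const State& S, const Topo& T, const FF& ff,
                        double out[6]) {
  double el[3], pr[3];
  elastic_sums(S, T, NULL, el);
  pair_sums_full(S, T, ff, pr);
  out[0] = el[0]; out[1] = el[1]; out[2] = el[2];
  out[3] = pr[0]; out[4] = pr[1]; out[5] = pr[2];
}

static State state_from_r(const NumericMatrix& pos, const NumericMatrix& v) {
  State S;
  S.P.resize(pos.nrow());
  for (int i = 0; i < pos.nrow(); i++) S.P[i] = Vec3(pos(i, 0), pos(i, 1), pos(i, 2));
  S.V.resize(v.nrow());
  for (int i = 0; i < v.nrow(); i++) S.V[i] = Vec3(v(i, 0), v(i, 1), v(i, 2));
  return S;
}

static void orthonormalize_v(State& S, int s) {
  Vec3 u = seg_u(S, s);
  Vec3 v = S.V[s] - dot(S.V[s], u) * u;
  double nv = norm(v);
  if (nv < 1e-9) {  // degenerate: rebuild a perpendicular
    Vec3 p = std::fabs(u.x) < 0.9 ? Vec3(1, 0, 0) : Vec3(0, 1, 0);
    v = p - dot(p, u) * u;
    nv = norm(v);
  }
  S.V[s] = (1.0 / nv) * v;
}

// ------------------------------------------------------------ R interface

// [[Rcpp::export]]
NumericVector cg_energy(NumericMatrix pos, NumericMatrix v, List topo, List ff) {
  Topo T = parse_topo(topo);
  FF F = parse_ff(ff);
  State S = state_from_r(pos, v);
  double e[6];
  full_energy(S, T, F, e);
  NumericVector out = NumericVector::create(
      _["stretch"] = e[0], _["bend"] = e[1], _["torsion"] = e[2],
      _["electrostatic"] = e[3], _["nucleosome"] = e[4],
      _["excluded_volume"] = e[5],
      _["total"] = e[0] + e[1] + e[2] + e[3] + e[4] + e[5]);
  return out;
}

// [[Rcpp::export]]
double cg_nuc_pair(NumericVector center_i, NumericVector axis_i,
                   NumericVector center_j, NumericVector axis_j, List ff) {
  FF F = parse_ff(ff);
  Vec3 ci(center_i[0], center_i[1], center_i[2]);
  Vec3 ai = unit(Vec3(axis_i[0], axis_i[1], axis_i[2]));
  Vec3 cj(center_j[0], center_j[1], center_j[2]);
  Vec3 aj = unit(Vec3(axis_j[0], axis_j[1], axis_j[2]));
  return nuc_pair_energy(ci, ai, cj, aj, F);
}

// [[Rcpp::export]]
List cg_stem_geom(NumericMatrix pos, NumericMatrix v, List topo) {
  Topo T = parse_topo(topo);
  State S = state_from_r(pos, v);
  NumericMatrix centers(T.n_stem, 3), axes(T.n_stem, 3);
  for (int k = 0; k < T.n_stem; k++) {
    Vec3 c, a;
    stem_geom(S, T, k, &c, &a);
    centers(k, 0) = c.x; centers(k, 1) = c.y; centers(k, 2) = c.z;
    axes(k, 0) = a.x; axes(k, 1) = a.y; axes(k, 2) = a.z;
  }
  return List::create(_["centers"] = centers, _["axes"] = axes);
}

// Metropolis Monte Carlo run at one temperature.
// One "step" is one attempted elementary move. Moves: local/crankshaft
// rotation of an interior stretch of joints about the chord, pivot rotation
// of a chain end, frame twist about a segment axis.
// [[Rcpp::export]]
List cg_mc_run(NumericMatrix pos, NumericMatrix v, List topo, List ff,
               double temperature, int n_steps,
               NumericVector amplitudes, NumericVector move_probs,
               int max_span, double seed, int sample_every,
               bool collect_configs, bool paranoid) {
  Topo T = parse_topo(topo);
  FF F = parse_ff(ff);
  State S = state_from_r(pos, v);
  const int n_seg = T.n_seg, n_joint = T.n_joint;
  if (n_seg < 2) stop("chain must have at least 2 segments");
  RNG rng((uint64_t)seed);

  double amp_crank = amplitudes[0], amp_pivot = amplitudes[1],
         amp_twist = amplitudes[2];
  double p_crank = move_probs[0], p_pivot = move_probs[1];

  std::vector<signed char> status(n_seg, ST_STATIC);
  std::vector<int> touched;
  State Snew = S;

  double e0[6];
  full_energy(S, T, F, e0);
  double e_run = e0[0] + e0[1] + e0[2] + e0[3] + e0[4] + e0[5];
  double max_drift = 0.0;

  long attempts[3] = {0, 0, 0}, accepts[3] = {0, 0, 0};
  int n_samples = sample_every > 0 ? n_steps / sample_every : 0;
  NumericMatrix samples(n_samples, 9);  // step, 6 terms, total, end2end
  List configs(collect_configs ? n_samples : 0);
  int si = 0;

  for (int step = 1; step <= n_steps; step++) {
    double um = rng.runif();
    int mtype;  // 0 crank, 1 pivot, 2 twist
    if (um < p_crank) mtype = 0;
    else if (um < p_crank + p_pivot) mtype = 1;
    else mtype = 2;
    attempts[mtype]++;

    touched.clear();
    Snew.P = S.P;
    Snew.V = S.V;
    bool frame_only = false;

    if (mtype == 0) {
      int span = 2 + rng.rint(std::max(1, max_span - 1));  // joints i..i+span
      if (span > n_joint - 1) span = n_joint - 1;
      int i = rng.rint(n_joint - span);
      int j = i + span;
      Vec3 axis = S.P[j] - S.P[i];
      double an = norm(axis);
      if (an < 1e-9) continue;
      axis = (1.0 / an) * axis;
      double ang = rng.runif(-amp_crank, amp_crank);
      for (int k = i + 1; k < j; k++)
        Snew.P[k] = S.P[i] + rotate_axis(S.P[k] - S.P[i], axis, ang);
      for (int s = i; s < j; s++) {
        touched.push_back(s);
        if (s > i && s < j - 1) {
          status[s] = ST_RIGID;
          Snew.V[s] = rotate_axis(S.V[s], axis, ang);
        } else {
          status[s] = ST_DEFORMED;
          Vec3 u_old = seg_u(S, s), u_new = seg_u(Snew, s);
          Snew.V[s] = min_rotate(S.V[s], u_old, u_new);
          orthonormalize_v(Snew, s);
        }
      }
    } else if (mtype == 1) {
      bool tail = rng.runif() < 0.5;
      int i = 1 + rng.rint(n_joint - 2);  // pivot joint, interior
      Vec3 axis = rng.rsphere();
      double ang = rng.runif(-amp_pivot, amp_pivot);
      if (tail) {
        for (int k = i + 1; k < n_joint; k++)
          Snew.P[k] = S.P[i] + rotate_axis(S.P[k] - S.P[i], axis, ang);
        for (int s = i; s < n_seg; s++) {
          touched.push_back(s);
          if (s == i) {
            status[s] = ST_DEFORMED;
            Snew.V[s] = min_rotate(S.V[s], seg_u(S, s), seg_u(Snew, s));
            orthonormalize_v(Snew, s);
          } else {
            status[s] = ST_RIGID;
            Snew.V[s] = rotate_axis(S.V[s], axis, ang);
          }
        }
      } else {
        for (int k = 0; k < i; k++)
          Snew.P[k] = S.P[i] + rotate_axis(S.P[k] - S.P[i], axis, ang);
        for (int s = 0; s < i; s++) {
          touched.push_back(s);
          if (s == i - 1) {
            status[s] = ST_DEFORMED;
            Snew.V[s] = min_rotate(S.V[s], seg_u(S, s), seg_u(Snew, s));
            orthonormalize_v(Snew, s);
          } else {
            status[s] = ST_RIGID;
            Snew.V[s] = rotate_axis(S.V[s], axis, ang);
          }
        }
      }
    } else {
      int s = rng.rint(n_seg);
      double ang = rng.runif(-amp_twist, amp_twist);
      Vec3 u = seg_u(S, s);
      Snew.V[s] = rotate_axis(S.V[s], u, ang);
      status[s] = ST_DEFORMED;
      touched.push_back(s);
      frame_only = !T.is_stem[s];
    }

    double de;
    double elo[3], eln[3];
    elastic_sums(S, T, &status[0], elo);
    elastic_sums(Snew, T, &status[0], eln);
    de = (eln[0] + eln[1] + eln[2]) - (elo[0] + elo[1] + elo[2]);
    if (!frame_only) {
      double pro[3], prn[3];
      pair_sums_partial(S, T, F, touched, &status[0], pro);
      pair_sums_partial(Snew, T, F, touched, &status[0], prn);
      de += (prn[0] + prn[1] + prn[2]) - (pro[0] + pro[1] + pro[2]);
    }

    bool accept = de <= 0.0 || rng.runif() < std::exp(-de / temperature);
    if (accept) {
      std::swap(S.P, Snew.P);
      std::swap(S.V, Snew.V);
      e_run += de;
      accepts[mtype]++;
    }
    for (size_t k = 0; k < touched.size(); k++) status[touched[k]] = ST_STATIC;

    if (sample_every > 0 && step % sample_every == 0) {
      if (paranoid) {  // incremental-vs-full check before any frame cleanup
        double ec[6];
        full_energy(S, T, F, ec);
        double etc = ec[0] + ec[1] + ec[2] + ec[3] + ec[4] + ec[5];
        max_drift = std::max(max_drift, std::fabs(etc - e_run));
      }
      for (int s = 0; s < n_seg; s++) orthonormalize_v(S, s);
      double e[6];
      full_energy(S, T, F, e);
      double etot = e[0] + e[1] + e[2] + e[3] + e[4] + e[5];
      e_run = etot;
      samples(si, 0) = step;
      for (int k = 0; k < 6; k++) samples(si, 1 + k) = e[k];
      samples(si, 7) = etot;
      Vec3 ee = S.P[n_joint - 1] - S.P[0];
      samples(si, 8) = norm(ee);
      if (collect_configs) {
        NumericMatrix cp(n_joint, 3), cv(n_seg, 3);
        for (int i = 0; i < n_joint; i++) {
          cp(i, 0) = S.P[i].x; cp(i, 1) = S.P[i].y; cp(i, 2) = S.P[i].z;
        }
        for (int i = 0; i < n_seg; i++) {
          cv(i, 0) = S.V[i].x; cv(i, 1) = S.V[i].y; cv(i, 2) = S.V[i].z;
        }
        configs[si] = List::create(_["pos"] = cp, _["v"] = cv);
      }
      si++;
    }
  }

  NumericMatrix out_pos(n_joint, 3), out_v(n_seg, 3);
  for (int i = 0; i < n_joint; i++) {
    out_pos(i, 0) = S.P[i].x; out_pos(i, 1) = S.P[i].y; out_pos(i, 2) = S.P[i].z;
  }
  for (int i = 0; i < n_seg; i++) {
    out_v(i, 0) = S.V[i].x; out_v(i, 1) = S.V[i].y; out_v(i, 2) = S.V[i].z;
  }
  double ef[6];
  full_energy(S, T, F, ef);
  NumericVector acc(3), att(3);
  for (int k = 0; k < 3; k++) { acc[k] = (double)accepts[k]; att[k] = (double)attempts[k]; }
  colnames(samples) = CharacterVector::create(
      "step", "stretch", "bend", "torsion", "electrostatic", "nucleosome",
      "excluded_volume", "total", "end_to_end");
  return List::create(
      _["pos"] = out_pos, _["v"] = out_v, _["samples"] = samples,
      _["configs"] = configs,
      _["accepts"] = acc, _["attempts"] = att,
      _["energy"] = NumericVector::create(
          _["stretch"] = ef[0], _["bend"] = ef[1], _["torsion"] = ef[2],
          _["electrostatic"] = ef[3], _["nucleosome"] = ef[4],
          _["excluded_volume"] = ef[5],
          _["total"] = ef[0] + ef[1] + ef[2] + ef[3] + ef[4] + ef[5]),
      _["max_drift"] = max_drift);
}
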