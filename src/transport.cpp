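// Analog photon-transport engine for the nested-cylinder HDR source model.
//
// Regions: 0 core (metallic Co), 1 encapsulation gap (air), 2 steel capsule,
// 3 steel drive cable, 4 phantom medium, -1 outside the phantom cube.
// Lengths cm, energies MeV. Kerma scored with the linear track-length
// estimator in full-azimuth ring cells; dose identified with collision
// kerma (no electron transport).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const double MEC2 = 0.51099895;           // electron rest energy, MeV
static const double MEVG_TO_GY = 1.602176634e-10; // (MeV/g) -> Gy
static const double BOUNDARY_EPS = 1e-8;          // cm, post-crossing nudge

// ---------------------------------------------------------------- RNG ------
// xoshiro256++ with splitmix64 seeding; one independent child stream per
// batch, derived from the root seed by a counter scheme.

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s[4];
  void seed(uint64_t root, uint64_t stream) {
    uint64_t x = root * 0x9E3779B97F4A7C15ULL + stream;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // in [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
};

// --------------------------------------------------------------- tables ----

struct XS {
  std::vector<double> logE, logMu, logMuEn;
  std::vector<double> fr[4];  // photo, incoh, coh, pair at nodes
  double density;
  double emin, emax;

  void load(const List &tab) {
    NumericVector E = tab["energy_MeV"], mu = tab["mu_rho"],
                  men = tab["mu_en_rho"];
    NumericVector f0 = tab["f_photo"], f1 = tab["f_incoh"],
                  f2 = tab["f_coh"], f3 = tab["f_pair"];
    density = as<double>(tab["density"]);
    int n = E.size();
    logE.resize(n); logMu.resize(n); logMuEn.resize(n);
    for (int j = 0; j < 4; ++j) fr[j].resize(n);
    for (int i = 0; i < n; ++i) {
      logE[i] = std::log(E[i]);
      logMu[i] = std::log(mu[i]);
      logMuEn[i] = std::log(men[i]);
      fr[0][i] = f0[i]; fr[1][i] = f1[i]; fr[2][i] = f2[i]; fr[3][i] = f3[i];
    }
    emin = E[0]; emax = E[n - 1];
  }

  inline int bracket(double logx) const {
    int lo = 0, hi = (int)logE.size() - 1;
    if (logx <= logE[0]) return 0;
    if (logx >= logE[hi]) return hi - 1;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (logE[mid] <= logx) lo = mid; else hi = mid;
    }
    return lo;
  }

  // log-log linear interpolation, clamped at the grid ends
  inline double mu_rho(double E) const {
    double lx = std::log(E);
    int i = bracket(lx);
    double w = (lx - logE[i]) / (logE[i + 1] - logE[i]);
    w = std::min(1.0, std::max(0.0, w));
    return std::exp(logMu[i] + w * (logMu[i + 1] - logMu[i]));
  }
  inline double mu_en_rho(double E) const {
    double lx = std::log(E);
    int i = bracket(lx);
    double w = (lx - logE[i]) / (logE[i + 1] - logE[i]);
    w = std::min(1.0, std::max(0.0, w));
    return std::exp(logMuEn[i] + w * (logMuEn[i + 1] - logMuEn[i]));
  }
  // branch fractions linear in log E; renormalized to unit sum
  inline void fractions(double E, double out[4]) const {
    double lx = std::log(E);
    int i = bracket(lx);
    double w = (lx - logE[i]) / (logE[i + 1] - logE[i]);
    w = std::min(1.0, std::max(0.0, w));
    double s = 0;
    for (int j = 0; j < 4; ++j) {
      out[j] = fr[j][i] + w * (fr[j][i + 1] - fr[j][i]);
      s += out[j];
    }
    for (int j = 0; j < 4; ++j) out[j] /= s;
    if (E < 2 * MEC2) {  // pair threshold is physical, not interpolated
      out[3] = 0.0;
      double s2 = out[0] + out[1] + out[2];
      for (int j = 0; j < 3; ++j) out[j] /= s2;
    }
  }
  // cumulative order: photoelectric, compton, rayleigh, pair
  inline int sample_kind(double E, double u) const {
    double f[4];
    fractions(E, f);
    double c = 0;
    for (int j = 0; j < 3; ++j) {
      c += f[j];
      if (u < c) return j;
    }
    return 3;
  }
};

static XS parse_xs(const List &tab) { XS x; x.load(tab); return x; }

// -------------------------------------------------------------- geometry ---

struct Geom {
  double r_core, h_core;     // active core radius / half-length
  double r_cap_in, r_cap;    // capsule inner & outer radii
  double h_cap;              // capsule half-length incl. flat end caps
  double z_cable_min;        // cable occupies z in [z_cable_min, -h_cap]
  double half;               // phantom cube half-side
  bool point_source;         // bare point emitter: whole cube is phantom

  void load(const List &g) {
    r_core = as<double>(g["r_core"]);
    h_core = as<double>(g["h_core"]);
    r_cap_in = as<double>(g["r_cap_in"]);
    r_cap = as<double>(g["r_cap"]);
    h_cap = as<double>(g["h_cap"]);
    z_cable_min = as<double>(g["z_cable_min"]);
    half = as<double>(g["half_side"]);
    point_source = as<bool>(g["point_source"]);
  }

  inline int locate(double x, double y, double z) const {
    if (std::fabs(x) > half || std::fabs(y) > half || std::fabs(z) > half)
      return -1;
    if (point_source) return 4;
    double r2 = x * x + y * y;
    if (r2 <= r_cap * r_cap) {
      if (z >= -h_cap && z <= h_cap) {
        if (r2 <= r_core * r_core && std::fabs(z) <= h_core) return 0;
        if (r2 <= r_cap_in * r_cap_in && std::fabs(z) <= h_core) return 1;
        return 2;
      }
      if (z >= z_cable_min && z < -h_cap) return 3;
    }
    return 4;
  }

  // smallest positive ray-surface crossing that changes the region
  inline double to_boundary(double x, double y, double z,
                            double dx, double dy, double dz,
                            int region, int &next) const {
    double cand[24];
    int nc = 0;
    // cube faces
    for (int ax = 0; ax < 3; ++ax) {
      double p = ax == 0 ? x : (ax == 1 ? y : z);
      double d = ax == 0 ? dx : (ax == 1 ? dy : dz);
      if (std::fabs(d) > 1e-14) {
        double t1 = (half - p) / d, t2 = (-half - p) / d;
        if (t1 > BOUNDARY_EPS) cand[nc++] = t1;
        if (t2 > BOUNDARY_EPS) cand[nc++] = t2;
      }
    }
    if (!point_source) {
      // cylinder walls
      double radii[3] = {r_core, r_cap_in, r_cap};
      double a = dx * dx + dy * dy;
      double b = 2.0 * (x * dx + y * dy);
      double r2 = x * x + y * y;
      for (int i = 0; i < 3; ++i) {
        if (a < 1e-20) continue;
        double cc = r2 - radii[i] * radii[i];
        double disc = b * b - 4 * a * cc;
        if (disc <= 0) continue;
        double sq = std::sqrt(disc);
        double t1 = (-b - sq) / (2 * a), t2 = (-b + sq) / (2 * a);
        if (t1 > BOUNDARY_EPS) cand[nc++] = t1;
        if (t2 > BOUNDARY_EPS) cand[nc++] = t2;
      }
      // axial planes
      double planes[5] = {-h_core, h_core, -h_cap, h_cap, z_cable_min};
      if (std::fabs(dz) > 1e-14) {
        for (int i = 0; i < 5; ++i) {
          double t = (planes[i] - z) / dz;
          if (t > BOUNDARY_EPS) cand[nc++] = t;
        }
      }
    }
    std::sort(cand, cand + nc);
    for (int i = 0; i < nc; ++i) {
      double t = cand[i];
      int reg = locate(x + (t + BOUNDARY_EPS) * dx,
                       y + (t + BOUNDARY_EPS) * dy,
                       z + (t + BOUNDARY_EPS) * dz);
      if (reg != region) { next = reg; return t; }
    }
    next = -1;  // numerical corner case: treat as escape at the cube
    double tesc = 2.0 * half * 1.7320508 + 1.0;
    return tesc;
  }
};

// ---------------------------------------------------------------- cells ----

struct Cell {
  double r1, r2, z1, z2, volume;
};

// chord length of segment p + t d, t in (0, tmax), inside the ring cell
static inline double chord_len(const Cell &c, double px, double py, double pz,
                               double dx, double dy, double dz, double tmax) {
  double lo = 0.0, hi = tmax;
  // z slab
  if (std::fabs(dz) < 1e-14) {
    if (pz < c.z1 || pz > c.z2) return 0.0;
  } else {
    double ta = (c.z1 - pz) / dz, tb = (c.z2 - pz) / dz;
    if (ta > tb) std::swap(ta, tb);
    lo = std::max(lo, ta); hi = std::min(hi, tb);
    if (hi <= lo) return 0.0;
  }
  double a = dx * dx + dy * dy;
  double b = 2.0 * (px * dx + py * dy);
  double r2now = px * px + py * py;
  double tin_lo = 1.0, tin_hi = 0.0;  // empty
  if (a < 1e-20) {
    // vertical ray: radial coordinate fixed
    if (r2now > c.r2 * c.r2 || r2now < c.r1 * c.r1) return 0.0;
    return hi - lo;
  }
  // inside outer cylinder
  double cc = r2now - c.r2 * c.r2;
  double disc = b * b - 4 * a * cc;
  if (disc <= 0) return 0.0;
  double sq = std::sqrt(disc);
  double to1 = (-b - sq) / (2 * a), to2 = (-b + sq) / (2 * a);
  lo = std::max(lo, to1); hi = std::min(hi, to2);
  if (hi <= lo) return 0.0;
  // exclude inner cylinder
  if (c.r1 > 0) {
    double ci = r2now - c.r1 * c.r1;
    double disci = b * b - 4 * a * ci;
    if (disci > 0) {
      double sqi = std::sqrt(disci);
      tin_lo = (-b - sqi) / (2 * a);
      tin_hi = (-b + sqi) / (2 * a);
    }
  }
  double len = hi - lo;
  if (tin_hi > tin_lo)
    len -= std::max(0.0, std::min(hi, tin_hi) - std::max(lo, tin_lo));
  return std::max(0.0, len);
}

// ------------------------------------------------------------- sampling ----

// Klein-Nishina: sample cos(theta) by rejection under a constant envelope.
// f(c) = r^2 (r + 1/r - 1 + c^2), r = 1/(1 + k(1-c)); f <= 2 with max at c=1.
static inline double kn_sample_cos(double E, Rng &rng) {
  double k = E / MEC2;
  for (;;) {
    double c = 2.0 * rng.unif() - 1.0;
    double r = 1.0 / (1.0 + k * (1.0 - c));
    double f = r * r * (r + 1.0 / r - 1.0 + c * c);
    if (2.0 * rng.unif() <= f) return c;
  }
}

// Thomson angular law for coherent (Rayleigh) redirection
static inline double thomson_sample_cos(Rng &rng) {
  for (;;) {
    double c = 2.0 * rng.unif() - 1.0;
    if (2.0 * rng.unif() <= 1.0 + c * c) return c;
  }
}

// rotate: new direction at polar angle (cos ct) and azimuth phi about d
static inline void rotate_direction(double &dx, double &dy, double &dz,
                                    double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cphi = std::cos(phi), sphi = std::sin(phi);
  double s2 = dx * dx + dy * dy;
  double nx, ny, nz;
  if (s2 > 1e-20) {
    double s = std::sqrt(s2);
    nx = dx * ct + st * (dx * dz * cphi - dy * sphi) / s;
    ny = dy * ct + st * (dy * dz * cphi + dx * sphi) / s;
    nz = dz * ct - st * s * cphi;
  } else {
    nx = st * cphi; ny = st * sphi; nz = (dz >= 0 ? ct : -ct);
  }
  double norm = std::sqrt(nx * nx + ny * ny + nz * nz);
  dx = nx / norm; dy = ny / norm; dz = nz / norm;
}

static inline void isotropic(Rng &rng, double &dx, double &dy, double &dz) {
  double ct = 2.0 * rng.unif() - 1.0;
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = 2.0 * M_PI * rng.unif();
  dx = st * std::cos(phi); dy = st * std::sin(phi); dz = ct;
}

struct Photon {
  double x, y, z, dx, dy, dz, E, w;
  int region;
};

// ------------------------------------------------------- main transport ----

struct Engine {
  Geom geom;
  std::vector<XS> xs;      // material tables
  std::vector<int> regmat; // region index -> material index (5 entries)
  std::vector<Cell> cells;
  int score_mat;           // material index of the scoring medium
  double cutoff, w133;
  bool vacuum, primary_only;
  double e_lines[2] = {1.17, 1.33};

  // per-run accumulators
  std::vector<double> cell_sum;      // current-batch kerma sums, Gy
  double n_compton = 0, n_rayleigh = 0, n_photo = 0, n_pair = 0,
         n_cutoff = 0, n_escaped = 0, n_created = 0, n_nonfinite = 0;
  double max_imbalance = 0;

  inline void score_segment(const Photon &p, double tmax) {
    double muen = xs[score_mat].mu_en_rho(p.E);
    double zlo = std::min(p.z, p.z + tmax * p.dz);
    double zhi = std::max(p.z, p.z + tmax * p.dz);
    for (size_t i = 0; i < cells.size(); ++i) {
      const Cell &c = cells[i];
      if (zhi < c.z1 || zlo > c.z2) continue;
      double l = chord_len(c, p.x, p.y, p.z, p.dx, p.dy, p.dz, tmax);
      if (l > 0)
        cell_sum[i] += p.w * p.E * muen * l / c.volume * MEVG_TO_GY;
    }
  }

  void emit(Rng &rng, Photon &p) {
    if (geom.point_source) {
      p.x = p.y = p.z = 0.0;
    } else {
      double rr = geom.r_core * std::sqrt(rng.unif());
      double phi = 2.0 * M_PI * rng.unif();
      p.x = rr * std::cos(phi);
      p.y = rr * std::sin(phi);
      p.z = (rng.unif() - 0.5) * 2.0 * geom.h_core;
    }
    isotropic(rng, p.dx, p.dy, p.dz);
    p.E = (rng.unif() < w133) ? e_lines[1] : e_lines[0];
    p.w = 1.0;
    p.region = geom.locate(p.x, p.y, p.z);
  }

  // transport one source photon and descendants; returns ledger imbalance
  void history(Rng &rng) {
    Photon stack[16];
    int nstack = 0;
    Photon p;
    emit(rng, p);
    double created = p.E, removed = 0, escaped = 0;
    n_created += 1;
    for (;;) {
      if (!(std::isfinite(p.x) && std::isfinite(p.E))) {  // diagnostic
        n_nonfinite += 1;
        break;
      }
      int mat = regmat[p.region];
      double mu = vacuum ? 0.0
                         : xs[mat].mu_rho(p.E) * xs[mat].density;
      double s = (mu > 0) ? -std::log(1.0 - rng.unif()) / mu
                          : std::numeric_limits<double>::infinity();
      int next;
      double db = geom.to_boundary(p.x, p.y, p.z, p.dx, p.dy, p.dz,
                                   p.region, next);
      if (s < db) {
        // interaction inside the current region
        score_segment(p, s);
        p.x += s * p.dx; p.y += s * p.dy; p.z += s * p.dz;
        if (primary_only) {
          removed += p.w * p.E; n_photo += 1;
        } else {
          int kind = xs[mat].sample_kind(p.E, rng.unif());
          if (kind == 0) {                       // photoelectric
            removed += p.w * p.E; n_photo += 1;
          } else if (kind == 1) {                // compton
            n_compton += 1;
            double c = kn_sample_cos(p.E, rng);
            double Eout = p.E / (1.0 + (p.E / MEC2) * (1.0 - c));
            removed += p.w * (p.E - Eout);
            if (Eout < cutoff) {
              removed += p.w * Eout; n_cutoff += 1;
            } else {
              rotate_direction(p.dx, p.dy, p.dz, c,
                               2.0 * M_PI * rng.unif());
              p.E = Eout;
              continue;
            }
          } else if (kind == 2) {                // rayleigh
            n_rayleigh += 1;
            double c = thomson_sample_cos(rng);
            rotate_direction(p.dx, p.dy, p.dz, c, 2.0 * M_PI * rng.unif());
            continue;
          } else {                               // pair production
            n_pair += 1;
            removed += p.w * (p.E - 2.0 * MEC2);  // kinetic, local kerma appx
            // the annihilation quanta return the 1.022 MeV taken from the
            // parent, so the energy ledger gains no new "created" term
            n_created += 2;
            Photon q = p;
            isotropic(rng, q.dx, q.dy, q.dz);
            q.E = MEC2;
            if (nstack < 15) {
              stack[nstack] = q;
              stack[nstack].dx = -q.dx; stack[nstack].dy = -q.dy;
              stack[nstack].dz = -q.dz;
              ++nstack;
            }
            p = q;
            continue;
          }
        }
      } else {
        // cross to the next region
        score_segment(p, db);
        double t = db + BOUNDARY_EPS;
        p.x += t * p.dx; p.y += t * p.dy; p.z += t * p.dz;
        if (next < 0) {
          escaped += p.w * p.E; n_escaped += 1;
        } else {
          p.region = next;
          continue;
        }
      }
      // current photon finished; pop a secondary if any
      if (nstack > 0) { p = stack[--nstack]; continue; }
      break;
    }
    double imb = std::fabs(created - removed - escaped) /
                 std::max(created, 1e-300);
    if (imb > max_imbalance) max_imbalance = imb;
  }
};

// ------------------------------------------------------------- exports -----

static Geom parse_geom(const List &g) { Geom gm; gm.load(g); return gm; }

static std::vector<Cell> parse_cells(const NumericMatrix &cm) {
  std::vector<Cell> cells(cm.nrow());
  for (int i = 0; i < cm.nrow(); ++i) {
    Cell c;
    c.r1 = cm(i, 0); c.r2 = cm(i, 1); c.z1 = cm(i, 2); c.z2 = cm(i, 3);
    c.volume = M_PI * (c.r2 * c.r2 - c.r1 * c.r1) * (c.z2 - c.z1);
    cells[i] = c;
  }
  return cells;
}

// [[Rcpp::export]]
NumericVector cpp_lookup(List table, NumericVector energy, int what) {
  XS x = parse_xs(table);
  int n = energy.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = (what == 0) ? x.mu_rho(energy[i]) : x.mu_en_rho(energy[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_branch_fractions(List table, double energy) {
  XS x = parse_xs(table);
  double f[4];
  x.fractions(energy, f);
  return NumericVector::create(f[0], f[1], f[2], f[3]);
}

// [[Rcpp::export]]
IntegerVector cpp_sample_interaction(List table, double energy,
                                     NumericVector u) {
  XS x = parse_xs(table);
  int n = u.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = x.sample_kind(energy, u[i]) + 1;
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_locate(List geom, NumericMatrix pts) {
  Geom g = parse_geom(geom);
  int n = pts.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = g.locate(pts(i, 0), pts(i, 1), pts(i, 2));
  return out;
}

// [[Rcpp::export]]
List cpp_boundary(List geom, NumericVector pos, NumericVector dir) {
  Geom g = parse_geom(geom);
  int region = g.locate(pos[0], pos[1], pos[2]);
  int next;
  double d = g.to_boundary(pos[0], pos[1], pos[2], dir[0], dir[1], dir[2],
                           region, next);
  return List::create(_["distance"] = d, _["next_region"] = next,
                      _["region"] = region);
}

// [[Rcpp::export]]
List cpp_sample_emission(List geom, int n, double seed, double w133) {
  Geom g = parse_geom(geom);
  Rng rng;
  rng.seed((uint64_t)seed, 0);
  NumericMatrix pos(n, 3), dir(n, 3);
  NumericVector energy(n);
  for (int i = 0; i < n; ++i) {
    double rr = g.r_core * std::sqrt(rng.unif());
    double phi = 2.0 * M_PI * rng.unif();
    pos(i, 0) = rr * std::cos(phi);
    pos(i, 1) = rr * std::sin(phi);
    pos(i, 2) = (rng.unif() - 0.5) * 2.0 * g.h_core;
    double dx, dy, dz;
    isotropic(rng, dx, dy, dz);
    dir(i, 0) = dx; dir(i, 1) = dy; dir(i, 2) = dz;
    energy[i] = (rng.unif() < w133) ? 1.33 : 1.17;
  }
  return List::create(_["position"] = pos, _["direction"] = dir,
                      _["energy"] = energy);
}

// [[Rcpp::export]]
NumericMatrix cpp_compton_sample(double energy, int n, double seed) {
  Rng rng;
  rng.seed((uint64_t)seed, 0);
  NumericMatrix out(n, 3);
  double k = energy / MEC2;
  for (int i = 0; i < n; ++i) {
    double c = kn_sample_cos(energy, rng);
    out(i, 0) = energy / (1.0 + k * (1.0 - c));
    out(i, 1) = c;
    out(i, 2) = 2.0 * M_PI * rng.unif();
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_thomson_sample(int n, double seed) {
  Rng rng;
  rng.seed((uint64_t)seed, 0);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = thomson_sample_cos(rng);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_score_segment(NumericMatrix cells, double mu_en_rho,
                                NumericVector start, NumericVector end,
                                double energy, double weight) {
  std::vector<Cell> cc = parse_cells(cells);
  double dx = end[0] - start[0], dy = end[1] - start[1],
         dz = end[2] - start[2];
  double len = std::sqrt(dx * dx + dy * dy + dz * dz);
  NumericVector out(cc.size());
  if (len <= 0) return out;
  dx /= len; dy /= len; dz /= len;
  for (size_t i = 0; i < cc.size(); ++i) {
    double l = chord_len(cc[i], start[0], start[1], start[2],
                         dx, dy, dz, len);
    out[i] = weight * energy * mu_en_rho * l / cc[i].volume * MEVG_TO_GY;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_run_simulation(List geom, List tables, IntegerVector region_mat,
                        int score_material, NumericMatrix cells,
                        double histories, int batches, double seed,
                        double cutoff, double w133, bool vacuum,
                        bool primary_only) {
  Engine eng;
  eng.geom = parse_geom(geom);
  for (int i = 0; i < tables.size(); ++i)
    eng.xs.push_back(parse_xs(tables[i]));
  eng.regmat.assign(region_mat.begin(), region_mat.end());
  eng.cells = parse_cells(cells);
  eng.score_mat = score_material;
  eng.cutoff = cutoff;
  eng.w133 = w133;
  eng.vacuum = vacuum;
  eng.primary_only = primary_only;

  int ncell = eng.cells.size();
  NumericMatrix batch_sums(batches, ncell);
  double per_batch = histories / batches;
  Rng rng;
  for (int b = 0; b < batches; ++b) {
    rng.seed((uint64_t)seed, (uint64_t)(b + 1));
    eng.cell_sum.assign(ncell, 0.0);
    long nb = (long)std::llround(per_batch);
    for (long h = 0; h < nb; ++h) eng.history(rng);
    for (int i = 0; i < ncell; ++i) batch_sums(b, i) = eng.cell_sum[i];
    Rcpp::checkUserInterrupt();
  }
  return List::create(
      _["batch_sums"] = batch_sums,
      _["histories"] = (double)((long)std::llround(per_batch) * batches),
      _["counters"] = List::create(
          _["created"] = eng.n_created, _["escaped"] = eng.n_escaped,
          _["photoelectric"] = eng.n_photo, _["compton"] = eng.n_compton,
          _["rayleigh"] = eng.n_rayleigh, _["pair"] = eng.n_pair,
          _["cutoff"] = eng.n_cutoff, _["nonfinite"] = eng.n_nonfinite),
      _["max_energy_imbalance"] = eng.max_imbalance);
}
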