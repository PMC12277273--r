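// Coarse-grained MD core: cell-list/Verlet neighbours, 12-6 LJ (truncated,
// shifted), bilinear breakable bonds, harmonic angles, Langevin thermostat,
// velocity-Verlet, axial box strain, virial stress tally.
//
// Units: kcal/mol, Angstrom, fs, Dalton. Only z is periodic.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// 1 Da (A/fs)^2 in kcal/mol
static const double MV2E = 1e7 / 4184.0;
static const double KB = 0.0019872041; // kcal/mol/K

// ---------------------------------------------------------------------------
// Deterministic RNG independent of R's stream: splitmix64 -> xoshiro256++
// ---------------------------------------------------------------------------
struct Xoshiro {
  uint64_t s[4];
  double cached;
  bool has_cached;
  explicit Xoshiro(uint64_t seed) : has_cached(false) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) { // splitmix64 seeding
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double gauss() { // Marsaglia polar, cached pair
    if (has_cached) { has_cached = false; return cached; }
    double u, v, s;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double f = std::sqrt(-2.0 * std::log(s) / s);
    cached = v * f;
    has_cached = true;
    return u * f;
  }
};

// ---------------------------------------------------------------------------
// System holds a snapshot plus topology/parameters in flat arrays
// ---------------------------------------------------------------------------
struct System {
  int N;
  std::vector<double> x, y, z, vx, vy, vz, fx, fy, fz, mass;
  std::vector<int> species;               // 0 = COL, 1 = HAP
  int nb;
  std::vector<int> b1, b2, btype;         // bond endpoints (0-based), type
  std::vector<char> broken;
  int na;
  std::vector<int> a1, a2, a3;            // angle triplets
  double ktheta;
  std::vector<double> theta0;             // per-angle, radians
  // pair tables indexed by species-pair key si + sj (0 colcol, 1 colhap, 2 haphap)
  double eps[3], sig[3], cutsq[3], shift[3], clampsq[3];
  // bond tables by type
  std::vector<double> br0, br1, brb, bKT0, bKT1, br1bar;
  double Lz;

  // exclusions: directly bonded pairs (small degree)
  std::vector<std::vector<int>> excl;

  inline double dz_mi(double d) const {
    if (d > 0.5 * Lz) d -= Lz; else if (d < -0.5 * Lz) d += Lz;
    return d;
  }
  void build_exclusions() {
    excl.assign(N, {});
    for (int b = 0; b < nb; ++b) {
      excl[b1[b]].push_back(b2[b]);
      excl[b2[b]].push_back(b1[b]);
    }
    for (auto &e : excl) std::sort(e.begin(), e.end());
  }
  inline bool excluded(int i, int j) const {
    const std::vector<int> &e = excl[i];
    return std::binary_search(e.begin(), e.end(), j);
  }
};

// ---------------------------------------------------------------------------
// Verlet neighbour list built from a cell list; half listing (j > i)
// ---------------------------------------------------------------------------
struct NeighborList {
  double rlist, rlistsq;
  std::vector<int> start, neigh; // CSR
  std::vector<double> x0, y0, z0; // positions at build time
  long n_builds = 0;

  void build(const System &s) {
    ++n_builds;
    const int N = s.N;
    double xlo = s.x[0], xhi = s.x[0], ylo = s.y[0], yhi = s.y[0];
    for (int i = 1; i < N; ++i) {
      xlo = std::min(xlo, s.x[i]); xhi = std::max(xhi, s.x[i]);
      ylo = std::min(ylo, s.y[i]); yhi = std::max(yhi, s.y[i]);
    }
    xlo -= 1e-6; ylo -= 1e-6;
    int ncx = std::max(1, (int)std::floor((xhi - xlo) / rlist) + 1);
    int ncy = std::max(1, (int)std::floor((yhi - ylo) / rlist) + 1);
    int ncz = std::max(1, (int)std::floor(s.Lz / rlist));
    double czw = s.Lz / ncz;
    bool z_all = ncz < 3; // too few periodic cells: scan all z layers
    std::vector<int> head(ncx * ncy * ncz, -1), nxt(N, -1), cellof(N);
    for (int i = 0; i < N; ++i) {
      int cx = (int)((s.x[i] - xlo) / rlist); if (cx >= ncx) cx = ncx - 1;
      int cy = (int)((s.y[i] - ylo) / rlist); if (cy >= ncy) cy = ncy - 1;
      double zi = s.z[i] - s.Lz * std::floor(s.z[i] / s.Lz);
      int cz = (int)(zi / czw); if (cz >= ncz) cz = ncz - 1;
      int c = (cz * ncy + cy) * ncx + cx;
      cellof[i] = c; nxt[i] = head[c]; head[c] = i;
    }
    start.assign(N + 1, 0);
    neigh.clear();
    neigh.reserve((size_t)N * 48);
    for (int i = 0; i < N; ++i) {
      start[i] = (int)neigh.size();
      int ci = cellof[i];
      int cx = ci % ncx, cy = (ci / ncx) % ncy, cz = ci / (ncx * ncy);
      for (int dzc = (z_all ? 0 : -1); dzc <= (z_all ? ncz - 1 : 1); ++dzc) {
        int zc = z_all ? dzc : (cz + dzc + ncz) % ncz;
        for (int dyc = -1; dyc <= 1; ++dyc) {
          int yc = cy + dyc; if (yc < 0 || yc >= ncy) continue;
          for (int dxc = -1; dxc <= 1; ++dxc) {
            int xc = cx + dxc; if (xc < 0 || xc >= ncx) continue;
            for (int j = head[(zc * ncy + yc) * ncx + xc]; j >= 0; j = nxt[j]) {
              if (j <= i) continue;
              double dx = s.x[i] - s.x[j];
              double dy = s.y[i] - s.y[j];
              double dz = s.dz_mi(s.z[i] - s.z[j]);
              if (dx * dx + dy * dy + dz * dz < rlistsq && !s.excluded(i, j))
                neigh.push_back(j);
            }
          }
        }
      }
    }
    start[N] = (int)neigh.size();
    x0 = s.x; y0 = s.y; z0 = s.z;
  }

  // max squared displacement since build (z drift from affine strain is
  // handled by rebuilding when the accumulated box change exceeds skin)
  double max_dispsq(const System &s) const {
    double m = 0.0;
    for (int i = 0; i < s.N; ++i) {
      double dx = s.x[i] - x0[i], dy = s.y[i] - y0[i];
      double dz = s.dz_mi(s.z[i] - z0[i]);
      double d = dx * dx + dy * dy + dz * dz;
      if (d > m) m = d;
    }
    return m;
  }
};

// ---------------------------------------------------------------------------
// Force evaluation; returns potential energy, accumulates virial diag
// ---------------------------------------------------------------------------
struct ForceResult {
  double epot;
  double wxx, wyy, wzz; // sum r_ij (x) f_ij over pairs/bonds/angles
  int newly_broken;
};

static ForceResult compute_forces(System &s, const NeighborList &nl,
                                  bool mark_breaks) {
  ForceResult out{0.0, 0.0, 0.0, 0.0, 0};
  std::fill(s.fx.begin(), s.fx.end(), 0.0);
  std::fill(s.fy.begin(), s.fy.end(), 0.0);
  std::fill(s.fz.begin(), s.fz.end(), 0.0);

  // LJ pairs. Mineral-free systems are single-species: hoist the
  // parameter lookups out of the inner loop in that common case.
  bool single = true;
  for (int i = 0; i < s.N; ++i) if (s.species[i] != 0) { single = false; break; }
  const double halfLz = 0.5 * s.Lz;
  if (single) {
    const double cutsq0 = s.cutsq[0], clampsq0 = s.clampsq[0];
    const double sig2 = s.sig[0] * s.sig[0];
    const double eps24 = 24.0 * s.eps[0], eps4 = 4.0 * s.eps[0],
                 shift0 = s.shift[0];
    for (int i = 0; i < s.N; ++i) {
      const double xi = s.x[i], yi = s.y[i], zi = s.z[i];
      double fxi = 0.0, fyi = 0.0, fzi = 0.0;
      for (int k = nl.start[i]; k < nl.start[i + 1]; ++k) {
        const int j = nl.neigh[k];
        double dx = xi - s.x[j], dy = yi - s.y[j];
        double dz = zi - s.z[j];
        if (dz > halfLz) dz -= s.Lz; else if (dz < -halfLz) dz += s.Lz;
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= cutsq0) continue;
        if (r2 < clampsq0) r2 = clampsq0;
        const double inv2 = 1.0 / r2;
        const double s2 = sig2 * inv2;
        const double s6 = s2 * s2 * s2;
        const double fpr = eps24 * (2.0 * s6 * s6 - s6) * inv2;
        out.epot += eps4 * (s6 * s6 - s6) - shift0;
        const double fx = fpr * dx, fy = fpr * dy, fz = fpr * dz;
        fxi += fx; fyi += fy; fzi += fz;
        s.fx[j] -= fx; s.fy[j] -= fy; s.fz[j] -= fz;
        out.wxx += dx * fx; out.wyy += dy * fy; out.wzz += dz * fz;
      }
      s.fx[i] += fxi; s.fy[i] += fyi; s.fz[i] += fzi;
    }
  } else {
  for (int i = 0; i < s.N; ++i) {
    const double xi = s.x[i], yi = s.y[i], zi = s.z[i];
    const int si = s.species[i];
    double fxi = 0.0, fyi = 0.0, fzi = 0.0;
    for (int k = nl.start[i]; k < nl.start[i + 1]; ++k) {
      const int j = nl.neigh[k];
      double dx = xi - s.x[j], dy = yi - s.y[j];
      double dz = s.dz_mi(zi - s.z[j]);
      double r2 = dx * dx + dy * dy + dz * dz;
      const int t = si + s.species[j];
      if (r2 >= s.cutsq[t]) continue;
      if (r2 < s.clampsq[t]) r2 = s.clampsq[t]; // 0.5*sigma safety clamp
      const double inv2 = 1.0 / r2;
      const double s2 = s.sig[t] * s.sig[t] * inv2;
      const double s6 = s2 * s2 * s2;
      const double fpr = 24.0 * s.eps[t] * (2.0 * s6 * s6 - s6) * inv2;
      out.epot += 4.0 * s.eps[t] * (s6 * s6 - s6) - s.shift[t];
      const double fx = fpr * dx, fy = fpr * dy, fz = fpr * dz;
      fxi += fx; fyi += fy; fzi += fz;
      s.fx[j] -= fx; s.fy[j] -= fy; s.fz[j] -= fz;
      out.wxx += dx * fx; out.wyy += dy * fy; out.wzz += dz * fz;
    }
    s.fx[i] += fxi; s.fy[i] += fyi; s.fz[i] += fzi;
  }
  }

  // bonds (bilinear, breakable)
  for (int b = 0; b < s.nb; ++b) {
    if (s.broken[b]) continue;
    const int i = s.b1[b], j = s.b2[b], t = s.btype[b];
    double dx = s.x[i] - s.x[j], dy = s.y[i] - s.y[j];
    double dz = s.dz_mi(s.z[i] - s.z[j]);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r >= s.brb[t]) {
      if (mark_breaks) { s.broken[b] = 1; ++out.newly_broken; }
      continue;
    }
    double fmag, e;
    if (r < s.br1[t]) {
      fmag = s.bKT0[t] * (r - s.br0[t]);
      e = 0.5 * s.bKT0[t] * (r - s.br0[t]) * (r - s.br0[t]);
    } else {
      fmag = s.bKT1[t] * (r - s.br1bar[t]);
      double e1 = 0.5 * s.bKT0[t] * (s.br1[t] - s.br0[t]) * (s.br1[t] - s.br0[t]);
      double h = [&]{ double d = r - s.br1bar[t], d1 = s.br1[t] - s.br1bar[t];
                      return 0.5 * s.bKT1[t] * (d * d - d1 * d1); }();
      e = e1 + h;
    }
    out.epot += e;
    const double fpr = -fmag / r; // restoring: pulls together when stretched
    const double fx = fpr * dx, fy = fpr * dy, fz = fpr * dz;
    s.fx[i] += fx; s.fy[i] += fy; s.fz[i] += fz;
    s.fx[j] -= fx; s.fy[j] -= fy; s.fz[j] -= fz;
    out.wxx += dx * fx; out.wyy += dy * fy; out.wzz += dz * fz;
  }

  // harmonic angles, E = K (theta - theta0)^2
  for (int a = 0; a < s.na; ++a) {
    const int i1 = s.a1[a], i2 = s.a2[a], i3 = s.a3[a];
    double d1x = s.x[i1] - s.x[i2], d1y = s.y[i1] - s.y[i2];
    double d1z = s.dz_mi(s.z[i1] - s.z[i2]);
    double d2x = s.x[i3] - s.x[i2], d2y = s.y[i3] - s.y[i2];
    double d2z = s.dz_mi(s.z[i3] - s.z[i2]);
    double rsq1 = d1x * d1x + d1y * d1y + d1z * d1z;
    double rsq2 = d2x * d2x + d2y * d2y + d2z * d2z;
    double r1 = std::sqrt(rsq1), r2 = std::sqrt(rsq2);
    double c = (d1x * d2x + d1y * d2y + d1z * d2z) / (r1 * r2);
    if (c > 1.0) c = 1.0; if (c < -1.0) c = -1.0;
    double sn = std::sqrt(1.0 - c * c);
    if (sn < 1e-8) sn = 1e-8; // collinear limit: transverse force -> 0
    double th = std::acos(c);
    double dth = th - s.theta0[a];
    out.epot += s.ktheta * dth * dth;
    double aa = -2.0 * s.ktheta * dth / sn;
    double a11 = aa * c / rsq1, a12 = -aa / (r1 * r2), a22 = aa * c / rsq2;
    double f1x = a11 * d1x + a12 * d2x;
    double f1y = a11 * d1y + a12 * d2y;
    double f1z = a11 * d1z + a12 * d2z;
    double f3x = a22 * d2x + a12 * d1x;
    double f3y = a22 * d2y + a12 * d1y;
    double f3z = a22 * d2z + a12 * d1z;
    s.fx[i1] += f1x; s.fy[i1] += f1y; s.fz[i1] += f1z;
    s.fx[i3] += f3x; s.fy[i3] += f3y; s.fz[i3] += f3z;
    s.fx[i2] -= f1x + f3x; s.fy[i2] -= f1y + f3y; s.fz[i2] -= f1z + f3z;
    out.wxx += d1x * f1x + d2x * f3x;
    out.wyy += d1y * f1y + d2y * f3y;
    out.wzz += d1z * f1z + d2z * f3z;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Marshalling R state <-> System
// ---------------------------------------------------------------------------
static System make_system(const List &state) {
  System s;
  NumericMatrix X = state["positions"];
  NumericMatrix V = state["velocities"];
  NumericVector M = state["mass"];
  IntegerVector sp = state["species"];
  IntegerMatrix B = state["bonds"];
  IntegerVector bt = state["bond_type"];
  LogicalVector br = state["broken"];
  IntegerMatrix A = state["angles"];
  NumericVector th0 = state["theta0"];
  List ff = state["ff_tables"];
  s.N = X.nrow();
  s.x.resize(s.N); s.y.resize(s.N); s.z.resize(s.N);
  s.vx.resize(s.N); s.vy.resize(s.N); s.vz.resize(s.N);
  s.fx.resize(s.N); s.fy.resize(s.N); s.fz.resize(s.N);
  s.mass.resize(s.N); s.species.resize(s.N);
  for (int i = 0; i < s.N; ++i) {
    s.x[i] = X(i, 0); s.y[i] = X(i, 1); s.z[i] = X(i, 2);
    s.vx[i] = V(i, 0); s.vy[i] = V(i, 1); s.vz[i] = V(i, 2);
    s.mass[i] = M[i]; s.species[i] = sp[i];
  }
  s.nb = B.nrow();
  s.b1.resize(s.nb); s.b2.resize(s.nb); s.btype.resize(s.nb);
  s.broken.resize(s.nb);
  for (int b = 0; b < s.nb; ++b) {
    s.b1[b] = B(b, 0) - 1; s.b2[b] = B(b, 1) - 1;
    s.btype[b] = bt[b]; s.broken[b] = br[b] ? 1 : 0;
  }
  s.na = A.nrow();
  s.a1.resize(s.na); s.a2.resize(s.na); s.a3.resize(s.na);
  s.theta0.resize(s.na);
  for (int a = 0; a < s.na; ++a) {
    s.a1[a] = A(a, 0) - 1; s.a2[a] = A(a, 1) - 1; s.a3[a] = A(a, 2) - 1;
    s.theta0[a] = th0[a];
  }
  s.ktheta = as<double>(ff["ktheta"]);
  NumericVector pe = ff["pair_eps"], ps = ff["pair_sigma"], pc = ff["pair_cutoff"];
  for (int t = 0; t < 3; ++t) {
    s.eps[t] = pe[t]; s.sig[t] = ps[t];
    s.cutsq[t] = pc[t] * pc[t];
    double sc6 = std::pow(ps[t] / pc[t], 6.0);
    s.shift[t] = 4.0 * pe[t] * (sc6 * sc6 - sc6);
    s.clampsq[t] = 0.25 * ps[t] * ps[t];
  }
  NumericVector r0 = ff["bond_r0"], r1 = ff["bond_r1"], rb = ff["bond_rb"],
    k0 = ff["bond_KT0"], k1 = ff["bond_KT1"], r1b = ff["bond_r1bar"];
  s.br0 = as<std::vector<double>>(r0); s.br1 = as<std::vector<double>>(r1);
  s.brb = as<std::vector<double>>(rb); s.bKT0 = as<std::vector<double>>(k0);
  s.bKT1 = as<std::vector<double>>(k1); s.br1bar = as<std::vector<double>>(r1b);
  List cell = state["cell"];
  s.Lz = as<double>(cell["Lz"]);
  s.build_exclusions();
  return s;
}

static double max_cutoff(const System &s) {
  double m = 0.0;
  for (int t = 0; t < 3; ++t) m = std::max(m, std::sqrt(s.cutsq[t]));
  return m;
}

// cross-section area: max(pi * R_p95^2, A_min). The radial percentile is
// taken over the collagen beads only: the reference fibril cylinder stays
// fixed as extrafibrillar mineral accretes (a growing normalization volume
// would make the modulus fall with mineral fraction, which contradicts the
// observed flat modulus across the insertion). A_min is the hexagonal-cell
// tiled area passed from R.
static double cross_area(const System &s, double p, double A_min) {
  double cx = 0.0, cy = 0.0;
  int n = 0;
  for (int i = 0; i < s.N; ++i)
    if (s.species[i] == 0) { cx += s.x[i]; cy += s.y[i]; ++n; }
  const bool all = n == 0; // no collagen: fall back to every bead
  if (all) { for (int i = 0; i < s.N; ++i) { cx += s.x[i]; cy += s.y[i]; } n = s.N; }
  cx /= n; cy /= n;
  std::vector<double> r2;
  r2.reserve(n);
  for (int i = 0; i < s.N; ++i) {
    if (!all && s.species[i] != 0) continue;
    double dx = s.x[i] - cx, dy = s.y[i] - cy;
    r2.push_back(dx * dx + dy * dy);
  }
  size_t k = (size_t)std::ceil(p * r2.size());
  if (k < 1) k = 1; if (k > r2.size()) k = r2.size();
  std::nth_element(r2.begin(), r2.begin() + (k - 1), r2.end());
  double A = M_PI * r2[k - 1];
  return std::max(A, A_min);
}

static void wrap_z(System &s) {
  for (int i = 0; i < s.N; ++i)
    s.z[i] -= s.Lz * std::floor(s.z[i] / s.Lz);
}

// [[Rcpp::export(name = ".md_forces_cpp")]]
List md_forces_cpp(List state, double skin = 2.0) {
  System s = make_system(state);
  NeighborList nl;
  nl.rlist = max_cutoff(s) + skin;
  nl.rlistsq = nl.rlist * nl.rlist;
  nl.build(s);
  ForceResult fr = compute_forces(s, nl, false);
  NumericMatrix F(s.N, 3);
  for (int i = 0; i < s.N; ++i) {
    F(i, 0) = s.fx[i]; F(i, 1) = s.fy[i]; F(i, 2) = s.fz[i];
  }
  return List::create(_["forces"] = F, _["epot"] = fr.epot,
                      _["virial"] = NumericVector::create(fr.wxx, fr.wyy, fr.wzz));
}

// [[Rcpp::export(name = ".md_run_cpp")]]
List md_run_cpp(List state, List opts) {
  System s = make_system(state);

  const long nsteps = (long)as<double>(opts["nsteps"]);
  const double dt = as<double>(opts["timestep"]);
  const bool thermo = as<bool>(opts["thermostat"]);
  const double Ttarget = as<double>(opts["temperature"]);
  const double damp = as<double>(opts["damping"]);
  const double strain_rate = as<double>(opts["strain_rate"]); // engineering, 1/fs
  const bool box_strain = as<bool>(opts["box_strain"]);
  const bool end_clamp = as<bool>(opts["end_clamp"]);
  const double clamp_width = as<double>(opts["clamp_width"]);
  const int record_interval = as<int>(opts["record_interval"]);
  const bool kinetic_virial = as<bool>(opts["kinetic_virial"]);
  const double A_hex = as<double>(opts["area_hex"]);
  const double vol_pctile = as<double>(opts["volume_percentile"]);
  const bool npt = as<bool>(opts["npt"]);
  const double npt_gain = as<double>(opts["npt_gain"]);       // 1/GPa
  const int npt_interval = as<int>(opts["npt_interval"]);
  const double npt_max_step = as<double>(opts["npt_max_step"]); // rel. Lz cap
  const double skin = as<double>(opts["skin"]);
  const uint64_t seed = (uint64_t)as<double>(opts["seed"]);

  Xoshiro rng(seed);
  const double Lz0 = s.Lz;
  wrap_z(s);

  NeighborList nl;
  nl.rlist = max_cutoff(s) + skin;
  nl.rlistsq = nl.rlist * nl.rlist;
  nl.build(s);
  double lz_at_build = s.Lz;

  // end-clamp bookkeeping: slabs by initial wrapped z
  std::vector<char> clamped(s.N, 0);
  std::vector<double> clampv(s.N, 0.0);
  if (end_clamp) {
    const double vpull = strain_rate * Lz0; // total separation speed
    double zmin = s.z[0], zmax = s.z[0];
    for (int i = 1; i < s.N; ++i) {
      zmin = std::min(zmin, s.z[i]); zmax = std::max(zmax, s.z[i]);
    }
    for (int i = 0; i < s.N; ++i) {
      if (s.z[i] < zmin + clamp_width) { clamped[i] = 1; clampv[i] = -0.5 * vpull; }
      else if (s.z[i] > zmax - clamp_width) { clamped[i] = 1; clampv[i] = 0.5 * vpull; }
      if (clamped[i]) s.vz[i] = clampv[i];
    }
  }

  // Langevin pre-factors (mechanical units: Da, A, fs). Friction and noise
  // are applied post-force once per step (the standard Langevin-as-force
  // scheme); the stored total force then feeds both Verlet half kicks.
  const double kT_mech = KB * Ttarget / MV2E;
  const double gam = (damp > 0) ? 1.0 / damp : 0.0;
  const double amp_c = std::sqrt(2.0 * kT_mech * gam / dt);
  std::vector<double> inv_mMV2E(s.N), sqm_amp(s.N);
  for (int i = 0; i < s.N; ++i) {
    inv_mMV2E[i] = 1.0 / (s.mass[i] * MV2E);
    sqm_amp[i] = std::sqrt(s.mass[i]) * amp_c * MV2E; // kcal/mol/A units
  }
  const double gMV2E = gam * MV2E;

  ForceResult fr = compute_forces(s, nl, true);
  if (thermo) {
    for (int i = 0; i < s.N; ++i) {
      const double mg = s.mass[i] * gMV2E;
      s.fx[i] += -mg * s.vx[i] + sqm_amp[i] * rng.gauss();
      s.fy[i] += -mg * s.vy[i] + sqm_amp[i] * rng.gauss();
      if (!(end_clamp && clamped[i]))
        s.fz[i] += -mg * s.vz[i] + sqm_amp[i] * rng.gauss();
    }
  }
  int broken_total = 0;
  for (int b = 0; b < s.nb; ++b) broken_total += s.broken[b];

  const long nrec = nsteps / record_interval;
  NumericVector rec_strain(nrec), rec_stress(nrec), rec_T(nrec),
    rec_epot(nrec), rec_ekin(nrec), rec_Lz(nrec), rec_time(nrec);
  IntegerVector rec_broken(nrec);
  long irec = 0;
  bool blew_up = false;
  double npt_acc = 0.0; long npt_n = 0;
  double A_cache = cross_area(s, vol_pctile, A_hex);

  for (long step = 1; step <= nsteps; ++step) {
    // half kick + drift (clamped beads: z prescribed, x/y free)
    for (int i = 0; i < s.N; ++i) {
      s.vx[i] += 0.5 * dt * s.fx[i] * inv_mMV2E[i];
      s.vy[i] += 0.5 * dt * s.fy[i] * inv_mMV2E[i];
      if (!(end_clamp && clamped[i]))
        s.vz[i] += 0.5 * dt * s.fz[i] * inv_mMV2E[i];
      s.x[i] += dt * s.vx[i]; s.y[i] += dt * s.vy[i]; s.z[i] += dt * s.vz[i];
    }
    // box strain: engineering rate w.r.t. the length at call time
    if (box_strain && strain_rate != 0.0) {
      double Lnew = Lz0 * (1.0 + strain_rate * dt * step);
      double scale = Lnew / s.Lz;
      for (int i = 0; i < s.N; ++i) s.z[i] *= scale;
      s.Lz = Lnew;
    }
    wrap_z(s);

    double drift = std::fabs(s.Lz - lz_at_build);
    if (4.0 * nl.max_dispsq(s) > (skin - drift > 0 ? (skin - drift) * (skin - drift) : 0.0)
        || drift > 0.5 * skin) {
      nl.build(s);
      lz_at_build = s.Lz;
    }
    fr = compute_forces(s, nl, true);
    broken_total += fr.newly_broken;
    if (thermo) {
      for (int i = 0; i < s.N; ++i) {
        const double mg = s.mass[i] * gMV2E;
        s.fx[i] += -mg * s.vx[i] + sqm_amp[i] * rng.gauss();
        s.fy[i] += -mg * s.vy[i] + sqm_amp[i] * rng.gauss();
        if (!(end_clamp && clamped[i]))
          s.fz[i] += -mg * s.vz[i] + sqm_amp[i] * rng.gauss();
      }
    }

    // second half kick + kinetic tallies
    double mv2zz = 0.0, mv2sum = 0.0;
    for (int i = 0; i < s.N; ++i) {
      s.vx[i] += 0.5 * dt * s.fx[i] * inv_mMV2E[i];
      s.vy[i] += 0.5 * dt * s.fy[i] * inv_mMV2E[i];
      if (!(end_clamp && clamped[i]))
        s.vz[i] += 0.5 * dt * s.fz[i] * inv_mMV2E[i];
      const double m = s.mass[i];
      mv2zz += m * s.vz[i] * s.vz[i];
      mv2sum += m * (s.vx[i] * s.vx[i] + s.vy[i] * s.vy[i] + s.vz[i] * s.vz[i]);
    }

    // cross-section refresh is cheap but not free: only at bookkeeping steps
    if (step % record_interval == 0 || (npt && npt_n + 1 >= npt_interval))
      A_cache = cross_area(s, vol_pctile, A_hex);
    double V = A_cache * s.Lz;
    double wzz = fr.wzz + (kinetic_virial ? mv2zz * MV2E : 0.0);
    double stress_zz = -wzz / V; // kcal/mol/A^3, tension positive

    if (npt) {
      npt_acc += stress_zz; ++npt_n;
      if ((int)npt_n == npt_interval) {
        double sbar = npt_acc / npt_n; // kcal/mol/A^3, tension positive
        double rel = -npt_gain * sbar;
        if (rel > npt_max_step) rel = npt_max_step;
        if (rel < -npt_max_step) rel = -npt_max_step;
        double scale = 1.0 + rel;
        for (int i = 0; i < s.N; ++i) s.z[i] *= scale;
        s.Lz *= scale;
        npt_acc = 0.0; npt_n = 0;
      }
    }

    if (step % record_interval == 0) {
      // re-zero net momentum under the thermostat
      if (thermo && !end_clamp) {
        double px = 0.0, py = 0.0, pz = 0.0, M = 0.0;
        for (int i = 0; i < s.N; ++i) {
          px += s.mass[i] * s.vx[i]; py += s.mass[i] * s.vy[i];
          pz += s.mass[i] * s.vz[i]; M += s.mass[i];
        }
        for (int i = 0; i < s.N; ++i) {
          s.vx[i] -= px / M; s.vy[i] -= py / M; s.vz[i] -= pz / M;
        }
      }
      double ekin = 0.5 * mv2sum * MV2E;
      rec_strain[irec] = box_strain ? (s.Lz - Lz0) / Lz0
                                    : strain_rate * dt * step;
      rec_stress[irec] = stress_zz;
      rec_T[irec] = mv2sum * MV2E / (3.0 * s.N * KB);
      rec_epot[irec] = fr.epot;
      rec_ekin[irec] = ekin;
      rec_Lz[irec] = s.Lz;
      rec_time[irec] = dt * step;
      rec_broken[irec] = broken_total;
      ++irec;
      if (!std::isfinite(fr.epot) || !std::isfinite(stress_zz)) {
        blew_up = true;
        break;
      }
      Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix X(s.N, 3), V(s.N, 3);
  for (int i = 0; i < s.N; ++i) {
    X(i, 0) = s.x[i]; X(i, 1) = s.y[i]; X(i, 2) = s.z[i];
    V(i, 0) = s.vx[i]; V(i, 1) = s.vy[i]; V(i, 2) = s.vz[i];
  }
  LogicalVector br(s.nb);
  for (int b = 0; b < s.nb; ++b) br[b] = s.broken[b] != 0;
  auto take = [&](const NumericVector &v) {
    NumericVector out(irec);
    for (long k = 0; k < irec; ++k) out[k] = v[k];
    return out;
  };
  IntegerVector rb_out(irec);
  for (long k = 0; k < irec; ++k) rb_out[k] = rec_broken[k];
  DataFrame rec = DataFrame::create(
    _["time"] = take(rec_time),
    _["strain"] = take(rec_strain),
    _["stress"] = take(rec_stress),
    _["temperature"] = take(rec_T),
    _["epot"] = take(rec_epot),
    _["ekin"] = take(rec_ekin),
    _["Lz"] = take(rec_Lz),
    _["broken_bonds"] = rb_out);
  return List::create(_["positions"] = X, _["velocities"] = V,
                      _["broken"] = br, _["Lz"] = s.Lz,
                      _["records"] = rec, _["blew_up"] = blew_up,
                      _["n_neighbor_builds"] = (double)nl.n_builds);
}

// ---------------------------------------------------------------------------
// Helpers for mineral placement: distance filtering and pair finding
// ---------------------------------------------------------------------------

// keep[i] = TRUE if points[i] is at least rcut from every row of existing
// (z-periodic with period Lz when Lz > 0)
// [[Rcpp::export(name = ".min_dist_keep_cpp")]]
LogicalVector min_dist_keep_cpp(NumericMatrix points, NumericMatrix existing,
                                double rcut, double Lz) {
  const int np = points.nrow(), ne = existing.nrow();
  LogicalVector keep(np, true);
  if (ne == 0 || np == 0) return keep;
  const double r2cut = rcut * rcut;
  // cell list over existing
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = existing(0, d); hi[d] = existing(0, d); }
  for (int i = 1; i < ne; ++i)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], existing(i, d));
      hi[d] = std::max(hi[d], existing(i, d));
    }
  int nc[3];
  for (int d = 0; d < 3; ++d) {
    lo[d] -= 1e-6;
    nc[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / rcut) + 1);
  }
  std::vector<int> head(nc[0] * nc[1] * nc[2], -1), nxt(ne, -1);
  auto cidx = [&](double x, double y, double z) {
    int cx = std::min(nc[0] - 1, std::max(0, (int)((x - lo[0]) / rcut)));
    int cy = std::min(nc[1] - 1, std::max(0, (int)((y - lo[1]) / rcut)));
    int cz = std::min(nc[2] - 1, std::max(0, (int)((z - lo[2]) / rcut)));
    return (cz * nc[1] + cy) * nc[0] + cx;
  };
  for (int i = 0; i < ne; ++i) {
    int c = cidx(existing(i, 0), existing(i, 1), existing(i, 2));
    nxt[i] = head[c]; head[c] = i;
  }
  for (int p = 0; p < np; ++p) {
    double px = points(p, 0), py = points(p, 1), pz = points(p, 2);
    for (int im = -1; im <= 1 && keep[p]; ++im) { // z images
      if (im != 0 && Lz <= 0) continue;
      double pzi = pz + im * Lz;
      int cx0 = (int)((px - lo[0]) / rcut), cy0 = (int)((py - lo[1]) / rcut),
          cz0 = (int)((pzi - lo[2]) / rcut);
      for (int cz = cz0 - 1; cz <= cz0 + 1 && keep[p]; ++cz) {
        if (cz < 0 || cz >= nc[2]) continue;
        for (int cy = cy0 - 1; cy <= cy0 + 1 && keep[p]; ++cy) {
          if (cy < 0 || cy >= nc[1]) continue;
          for (int cx = cx0 - 1; cx <= cx0 + 1 && keep[p]; ++cx) {
            if (cx < 0 || cx >= nc[0]) continue;
            for (int i = head[(cz * nc[1] + cy) * nc[0] + cx]; i >= 0; i = nxt[i]) {
              double dx = px - existing(i, 0), dy = py - existing(i, 1),
                     dz = pzi - existing(i, 2);
              if (dx * dx + dy * dy + dz * dz < r2cut) { keep[p] = false; break; }
            }
          }
        }
      }
    }
  }
  return keep;
}

// all pairs (i from A, j from B) with distance < rcut; 1-based indices.
// When B has zero rows, finds pairs within A itself (i < j).
// [[Rcpp::export(name = ".close_pairs_cpp")]]
IntegerMatrix close_pairs_cpp(NumericMatrix A, NumericMatrix B,
                              double rcut, double Lz) {
  const bool self = B.nrow() == 0;
  const NumericMatrix &E = self ? A : B;
  const int na = A.nrow(), ne = E.nrow();
  const double r2cut = rcut * rcut;
  std::vector<int> out_i, out_j;
  for (int i = 0; i < na; ++i) {
    for (int j = self ? i + 1 : 0; j < ne; ++j) {
      double dx = A(i, 0) - E(j, 0), dy = A(i, 1) - E(j, 1),
             dz = A(i, 2) - E(j, 2);
      if (Lz > 0) { dz -= Lz * std::nearbyint(dz / Lz); }
      if (dx * dx + dy * dy + dz * dz < r2cut) {
        out_i.push_back(i + 1); out_j.push_back(j + 1);
      }
    }
  }
  IntegerMatrix P(out_i.size(), 2);
  for (size_t k = 0; k < out_i.size(); ++k) {
    P(k, 0) = out_i[k]; P(k, 1) = out_j[k];
  }
  return P;
}
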