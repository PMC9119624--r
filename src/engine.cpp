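// Core numerics: bonded + non-bonded forces, BAOAB Langevin integrator,
// Verlet neighbor list, and per-frame contact/cluster counting.
//
// Unit system (shared with the R layer): lengths in Angstrom, time in fs,
// energies in kcal/mol, masses in Da.  Accelerations need the mechanical
// conversion  1 kcal/mol/A / Da = 4.184e-4 A/fs^2.
//
// Bead roles are encoded as integers:
//   0 = specific, 1 = nonspecific, 2 = inert, 3 = alt_nonspecific

#include <Rcpp.h>
#include <cstdint>
#include <cstdio>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double KCAL_PER_DA_TO_A_FS2 = 4.184e-4;
static const double KB_KCAL = 0.0019872041; // kcal/mol/K

// ---------------------------------------------------------------------------
// RNG: xoshiro256** seeded through splitmix64.  State is serialized to/from
// four 16-digit hex strings so R can checkpoint and restart runs exactly.
// ---------------------------------------------------------------------------

struct Xoshiro256 {
  uint64_t s[4];

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on [0, 1)
  double unif() { return (next() >> 11) * 0x1.0p-53; }

  // standard normals by Marsaglia's polar method, filled in pairs so the
  // stream position is a pure function of how many values were requested
  void fill_gauss(double *out, int n) {
    int i = 0;
    while (i < n) {
      double u, v, r2;
      do {
        u = 2.0 * unif() - 1.0;
        v = 2.0 * unif() - 1.0;
        r2 = u * u + v * v;
      } while (r2 >= 1.0 || r2 == 0.0);
      const double f = std::sqrt(-2.0 * std::log(r2) / r2);
      out[i++] = u * f;
      if (i < n) out[i++] = v * f;
    }
  }

  void seed(uint64_t x) {
    // splitmix64 expansion of a single seed word
    for (int k = 0; k < 4; ++k) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[k] = z ^ (z >> 31);
    }
  }
};

static CharacterVector rng_serialize(const Xoshiro256 &g) {
  CharacterVector out(4);
  char buf[17];
  for (int k = 0; k < 4; ++k) {
    std::snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)g.s[k]);
    out[k] = buf;
  }
  return out;
}

static uint64_t parse_hex64(const char *s) {
  uint64_t v = 0;
  for (; *s; ++s) {
    int d;
    if (*s >= '0' && *s <= '9') d = *s - '0';
    else if (*s >= 'a' && *s <= 'f') d = *s - 'a' + 10;
    else if (*s >= 'A' && *s <= 'F') d = *s - 'A' + 10;
    else stop("invalid hex digit in rng state");
    v = (v << 4) | (uint64_t)d;
  }
  return v;
}

static Xoshiro256 rng_deserialize(const CharacterVector &state) {
  if (state.size() != 4) stop("rng state must be 4 hex strings");
  Xoshiro256 g;
  for (int k = 0; k < 4; ++k) {
    g.s[k] = parse_hex64(CHAR(STRING_ELT(state, k)));
  }
  return g;
}

// [[Rcpp::export]]
CharacterVector cpp_seed_rng(int seed) {
  Xoshiro256 g;
  g.seed((uint64_t)(uint32_t)seed);
  return rng_serialize(g);
}

// ---------------------------------------------------------------------------
// Topology helpers
// ---------------------------------------------------------------------------

struct Topology {
  int n;
  std::vector<int> role, chain;
  std::vector<int> bond_i, bond_j;        // chain-internal (i, i+1)
  std::vector<int> ang_i;                 // angle triples (i, i+1, i+2)
};

static Topology make_topology(const IntegerVector &role,
                              const IntegerVector &chain) {
  Topology top;
  top.n = role.size();
  if (chain.size() != top.n) stop("role/chain length mismatch");
  top.role.assign(role.begin(), role.end());
  top.chain.assign(chain.begin(), chain.end());
  for (int i = 0; i + 1 < top.n; ++i) {
    if (top.chain[i + 1] < top.chain[i])
      stop("chain ids must be non-decreasing with bead index");
    if (top.chain[i] == top.chain[i + 1]) {
      top.bond_i.push_back(i);
      top.bond_j.push_back(i + 1);
    }
  }
  for (int i = 0; i + 2 < top.n; ++i) {
    if (top.chain[i] == top.chain[i + 1] && top.chain[i] == top.chain[i + 2])
      top.ang_i.push_back(i);
  }
  return top;
}

// minimum-image displacement; exact for coordinates wrapped into [0, box)
static inline double min_image(double d, double box, double invbox) {
  (void)invbox;
  if (d > 0.5 * box) d -= box;
  else if (d < -0.5 * box) d += box;
  return d;
}

// wrap coordinates into [0, box): required before min_image-based kernels
static void wrap_coords(std::vector<double> &x, double box) {
  for (size_t k = 0; k < x.size(); ++k)
    x[k] -= box * std::floor(x[k] / box);
}

// ---------------------------------------------------------------------------
// Pair (Verlet) list.  Built by a direct O(N^2) scan: systems here are at
// most a few thousand beads, where the scan is cheaper and simpler than cell
// binning.  Per-pair LJ prefactors and squared cutoffs are frozen at build
// time.  `skin < 0` means "all non-excluded pairs" (naive evaluation path).
// ---------------------------------------------------------------------------

struct PairList {
  std::vector<int> i, j;
  std::vector<double> eps4, cut2;         // 4*eps (kcal/mol), cutoff^2
  std::vector<double> ref;                // positions at build time
  double rlist2;                          // (max cutoff + skin)^2, <0 if all
};

struct PairParams {
  double eps4[4][4];                      // 4*eps, kcal/mol; 0 => inactive
  double cut2[4][4];
};

static PairParams make_pair_params(const NumericMatrix &eps,
                                   const NumericMatrix &rcut) {
  if (eps.nrow() != 4 || eps.ncol() != 4 || rcut.nrow() != 4 || rcut.ncol() != 4)
    stop("eps and rcut must be 4x4 matrices");
  PairParams pp;
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b) {
      pp.eps4[a][b] = 4.0 * eps(a, b);
      pp.cut2[a][b] = rcut(a, b) * rcut(a, b);
    }
  return pp;
}

static inline void maybe_add_pair(PairList &pl, const std::vector<double> &x,
                                  const Topology &top, const PairParams &pp,
                                  double box, double invbox, double rlist2,
                                  int i, int j) {
  if (top.chain[i] == top.chain[j] && std::abs(j - i) == 1) return; // 1-2
  const double e4 = pp.eps4[top.role[i]][top.role[j]];
  if (e4 == 0.0) return;  // zero-depth pairs do not interact
  const double dx = min_image(x[3 * i] - x[3 * j], box, invbox);
  const double dy = min_image(x[3 * i + 1] - x[3 * j + 1], box, invbox);
  const double dz = min_image(x[3 * i + 2] - x[3 * j + 2], box, invbox);
  if (dx * dx + dy * dy + dz * dz > rlist2) return;
  if (i < j) { pl.i.push_back(i); pl.j.push_back(j); }
  else       { pl.i.push_back(j); pl.j.push_back(i); }
  pl.eps4.push_back(e4);
  pl.cut2.push_back(pp.cut2[top.role[i]][top.role[j]]);
}

static void build_pair_list(PairList &pl, const std::vector<double> &x,
                            const Topology &top, const PairParams &pp,
                            double box, double skin, double maxcut) {
  const int n = top.n;
  const double invbox = 1.0 / box;
  pl.i.clear(); pl.j.clear(); pl.eps4.clear(); pl.cut2.clear();
  const bool all = (skin < 0);
  const double rl = maxcut + (all ? 0.0 : skin);
  pl.rlist2 = all ? -1.0 : rl * rl;

  int nc = all ? 0 : (int)std::floor(box / rl);
  // cap the grid so the cell table stays O(N) even in very dilute boxes
  const int nc_cap = (int)std::cbrt(8.0 * n) + 1;
  if (nc > nc_cap) nc = nc_cap;
  if (all || nc < 3) {
    // direct scan: naive path, tiny systems, or boxes too small to bin
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        if (all) {
          if (top.chain[i] == top.chain[j] && j - i == 1) continue;
          const double e4 = pp.eps4[top.role[i]][top.role[j]];
          if (e4 == 0.0) continue;
          pl.i.push_back(i); pl.j.push_back(j);
          pl.eps4.push_back(e4);
          pl.cut2.push_back(pp.cut2[top.role[i]][top.role[j]]);
        } else {
          maybe_add_pair(pl, x, top, pp, box, invbox, pl.rlist2, i, j);
        }
      }
    }
  } else {
    // cell-binned scan over the 13 half-neighbor offsets + own cell
    const double cw = box / nc;
    const int ncell = nc * nc * nc;
    std::vector<int> head(ncell, -1), next(n, -1), cell_of(n);
    for (int i = 0; i < n; ++i) {
      int cx = (int)(x[3 * i] / cw), cy = (int)(x[3 * i + 1] / cw),
          cz = (int)(x[3 * i + 2] / cw);
      if (cx >= nc) cx = nc - 1; if (cy >= nc) cy = nc - 1;
      if (cz >= nc) cz = nc - 1;
      if (cx < 0) cx = 0; if (cy < 0) cy = 0; if (cz < 0) cz = 0;
      const int c = (cx * nc + cy) * nc + cz;
      cell_of[i] = c;
      next[i] = head[c];
      head[c] = i;
    }
    static const int off[13][3] = {
      {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
      {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};
    // bead-centric: own-cell pairs (via list order) + 13 half-neighbor cells
    for (int i = 0; i < n; ++i) {
      for (int j = next[i]; j >= 0; j = next[j])
        maybe_add_pair(pl, x, top, pp, box, invbox, pl.rlist2, i, j);
      const int c = cell_of[i];
      const int cz = c % nc, cy = (c / nc) % nc, cx = c / (nc * nc);
      for (int k = 0; k < 13; ++k) {
        const int ox = (cx + off[k][0] + nc) % nc;
        const int oy = (cy + off[k][1] + nc) % nc;
        const int oz = (cz + off[k][2] + nc) % nc;
        for (int j = head[(ox * nc + oy) * nc + oz]; j >= 0; j = next[j])
          maybe_add_pair(pl, x, top, pp, box, invbox, pl.rlist2, i, j);
      }
    }
  }
  pl.ref = x;
}

static bool list_stale(const PairList &pl, const std::vector<double> &x,
                       double box, double half_skin2) {
  if (pl.rlist2 < 0) return false;        // naive path never rebuilds
  const double invbox = 1.0 / box;
  const int n = (int)x.size() / 3;
  for (int i = 0; i < n; ++i) {
    double dx = min_image(x[3 * i] - pl.ref[3 * i], box, invbox);
    double dy = min_image(x[3 * i + 1] - pl.ref[3 * i + 1], box, invbox);
    double dz = min_image(x[3 * i + 2] - pl.ref[3 * i + 2], box, invbox);
    if (dx * dx + dy * dy + dz * dz > half_skin2) return true;
  }
  return false;
}

// ---------------------------------------------------------------------------
// Forces.  Energy terms follow the model exactly:
//   stretching  E = k_s * (r - r0)^2            (no 1/2 prefactor)
//   bending     E = kappa * (1 - cos theta)
//   non-bonded  E = 4 eps [ (s/r)^12 - (s/r)^6 ], truncated unshifted
// ---------------------------------------------------------------------------

struct EnergyTerms { double stretch, bend, pair; };

static EnergyTerms compute_forces(const std::vector<double> &x,
                                  std::vector<double> &f,
                                  const Topology &top, const PairList &pl,
                                  double box, double ks, double r0,
                                  double kappa, double sigma2) {
  const double invbox = 1.0 / box;
  std::fill(f.begin(), f.end(), 0.0);
  EnergyTerms e = {0.0, 0.0, 0.0};

  // bonds
  for (size_t b = 0; b < top.bond_i.size(); ++b) {
    const int i = top.bond_i[b], j = top.bond_j[b];
    const double dx = min_image(x[3 * i] - x[3 * j], box, invbox);
    const double dy = min_image(x[3 * i + 1] - x[3 * j + 1], box, invbox);
    const double dz = min_image(x[3 * i + 2] - x[3 * j + 2], box, invbox);
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r <= 0.0) stop("zero-length bond between beads %d and %d", i + 1, j + 1);
    const double dr = r - r0;
    e.stretch += ks * dr * dr;
    const double fac = -2.0 * ks * dr / r;  // F_i = fac * (r_i - r_j)
    f[3 * i] += fac * dx; f[3 * i + 1] += fac * dy; f[3 * i + 2] += fac * dz;
    f[3 * j] -= fac * dx; f[3 * j + 1] -= fac * dy; f[3 * j + 2] -= fac * dz;
  }

  // angles: theta between consecutive bond vectors, zero when straight
  for (size_t a = 0; a < top.ang_i.size(); ++a) {
    const int i = top.ang_i[a];
    double u[3], v[3];
    for (int d = 0; d < 3; ++d) {
      u[d] = min_image(x[3 * (i + 1) + d] - x[3 * i + d], box, invbox);
      v[d] = min_image(x[3 * (i + 2) + d] - x[3 * (i + 1) + d], box, invbox);
    }
    const double nu2 = u[0] * u[0] + u[1] * u[1] + u[2] * u[2];
    const double nv2 = v[0] * v[0] + v[1] * v[1] + v[2] * v[2];
    if (nu2 <= 0.0 || nv2 <= 0.0)
      stop("zero-length bond in angle at bead %d", i + 1);
    const double nu = std::sqrt(nu2), nv = std::sqrt(nv2);
    const double dot = u[0] * v[0] + u[1] * v[1] + u[2] * v[2];
    const double c = dot / (nu * nv);
    e.bend += kappa * (1.0 - c);
    // gradients of cos(theta) wrt the two bond vectors
    for (int d = 0; d < 3; ++d) {
      const double gu = v[d] / (nu * nv) - c * u[d] / nu2;
      const double gv = u[d] / (nu * nv) - c * v[d] / nv2;
      // E = kappa (1 - cos): dE/du = -kappa * gu, u = r_{i+1} - r_i, ...
      f[3 * i + d]       += -kappa * gu;
      f[3 * (i + 1) + d] +=  kappa * gu - kappa * gv;
      f[3 * (i + 2) + d] +=  kappa * gv;
    }
  }

  // non-bonded pairs
  const size_t np = pl.i.size();
  for (size_t p = 0; p < np; ++p) {
    const int i = pl.i[p], j = pl.j[p];
    const double dx = min_image(x[3 * i] - x[3 * j], box, invbox);
    const double dy = min_image(x[3 * i + 1] - x[3 * j + 1], box, invbox);
    const double dz = min_image(x[3 * i + 2] - x[3 * j + 2], box, invbox);
    const double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= pl.cut2[p]) continue;
    const double inv_r2 = 1.0 / r2;
    const double s2 = sigma2 * inv_r2;
    const double s6 = s2 * s2 * s2;
    const double s12 = s6 * s6;
    const double e4 = pl.eps4[p];
    e.pair += e4 * (s12 - s6);
    const double fac = 6.0 * e4 * (2.0 * s12 - s6) * inv_r2; // F_i = fac * dr
    f[3 * i] += fac * dx; f[3 * i + 1] += fac * dy; f[3 * i + 2] += fac * dz;
    f[3 * j] -= fac * dx; f[3 * j + 1] -= fac * dy; f[3 * j + 2] -= fac * dz;
  }
  return e;
}

static double max_cutoff(const PairParams &pp) {
  double m = 0.0;
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b)
      if (pp.eps4[a][b] != 0.0 && pp.cut2[a][b] > m) m = pp.cut2[a][b];
  return std::sqrt(m);
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix pos, IntegerVector role,
                       IntegerVector chain, double box, List par,
                       NumericMatrix eps, NumericMatrix rcut) {
  const Topology top = make_topology(role, chain);
  const int n = top.n;
  if (pos.nrow() != n || pos.ncol() != 3) stop("positions must be N x 3");
  const double ks = par["ks"], r0 = par["r0"], kappa = par["kappa"],
               sigma = par["sigma"];
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = pos(i, d);
  wrap_coords(x, box);

  const PairParams pp = make_pair_params(eps, rcut);
  PairList pl;
  build_pair_list(pl, x, top, pp, box, -1.0, max_cutoff(pp));

  // close-overlap warning (diagnostic path only)
  const double invbox = 1.0 / box;
  const double warn2 = 0.09 * sigma * sigma;
  for (size_t p = 0; p < pl.i.size(); ++p) {
    const int i = pl.i[p], j = pl.j[p];
    double dx = min_image(x[3 * i] - x[3 * j], box, invbox);
    double dy = min_image(x[3 * i + 1] - x[3 * j + 1], box, invbox);
    double dz = min_image(x[3 * i + 2] - x[3 * j + 2], box, invbox);
    if (dx * dx + dy * dy + dz * dz < warn2) {
      warning("beads %d and %d closer than 0.3 sigma", i + 1, j + 1);
      break;
    }
  }

  std::vector<double> f(3 * n);
  // evaluate each term separately so tests can check analytic gradients
  NumericMatrix fs(n, 3), fb(n, 3), fp(n, 3);
  EnergyTerms et;
  {
    Topology t2 = top; t2.ang_i.clear();
    PairList empty; empty.rlist2 = -1.0;
    et = compute_forces(x, f, t2, empty, box, ks, r0, kappa, sigma * sigma);
    for (int i = 0; i < n; ++i) for (int d = 0; d < 3; ++d) fs(i, d) = f[3 * i + d];
  }
  double e_stretch = et.stretch;
  {
    Topology t2 = top; t2.bond_i.clear(); t2.bond_j.clear();
    PairList empty; empty.rlist2 = -1.0;
    et = compute_forces(x, f, t2, empty, box, ks, r0, kappa, sigma * sigma);
    for (int i = 0; i < n; ++i) for (int d = 0; d < 3; ++d) fb(i, d) = f[3 * i + d];
  }
  double e_bend = et.bend;
  {
    Topology t2 = top; t2.bond_i.clear(); t2.bond_j.clear(); t2.ang_i.clear();
    et = compute_forces(x, f, t2, pl, box, ks, r0, kappa, sigma * sigma);
    for (int i = 0; i < n; ++i) for (int d = 0; d < 3; ++d) fp(i, d) = f[3 * i + d];
  }
  double e_pair = et.pair;

  return List::create(_["e_stretch"] = e_stretch, _["e_bend"] = e_bend,
                      _["e_pair"] = e_pair, _["f_stretch"] = fs,
                      _["f_bend"] = fb, _["f_pair"] = fp);
}

// ---------------------------------------------------------------------------
// BAOAB Langevin integrator
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, NumericMatrix vel, IntegerVector role,
             IntegerVector chain, double box, double time0, List par,
             NumericMatrix eps, NumericMatrix rcut, int n_steps,
             int report_every, CharacterVector rng_state, bool use_nlist) {
  if (n_steps < 1) stop("n_steps must be >= 1");
  if (report_every < 1) stop("report_every must be >= 1");
  const Topology top = make_topology(role, chain);
  const int n = top.n;
  if (pos.nrow() != n || vel.nrow() != n) stop("positions/velocities must be N x 3");

  const double ks = par["ks"], r0 = par["r0"], kappa = par["kappa"],
               sigma = par["sigma"], dt = par["dt"], T = par["T"],
               damping_fs = par["damping_fs"], mass = par["mass"];
  const double sigma2 = sigma * sigma;
  const double inv_m = 1.0 / mass;
  const double acc_fac = KCAL_PER_DA_TO_A_FS2 * inv_m; // force -> A/fs^2
  // O-step: exact Ornstein-Uhlenbeck update with gamma = 1/damping
  const double c1 = std::exp(-dt / damping_fs);
  const double c2 = std::sqrt((1.0 - c1 * c1) * KB_KCAL * T *
                              KCAL_PER_DA_TO_A_FS2 * inv_m);
  const double kin_fac = mass / KCAL_PER_DA_TO_A_FS2 / (3.0 * n * KB_KCAL);

  std::vector<double> x(3 * n), v(3 * n), f(3 * n), g(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      x[3 * i + d] = pos(i, d);
      v[3 * i + d] = vel(i, d);
    }
  wrap_coords(x, box);

  Xoshiro256 rng = rng_deserialize(rng_state);
  const PairParams pp = make_pair_params(eps, rcut);
  const double maxcut = max_cutoff(pp);
  const double skin = use_nlist ? 0.5 * sigma : -1.0;
  const double half_skin2 = 0.25 * skin * skin;
  PairList pl;
  build_pair_list(pl, x, top, pp, box, skin, maxcut);
  int n_rebuilds = 0;

  const int n_frames = n_steps / report_every + 1;
  NumericVector frames(Dimension(n, 3, n_frames));
  NumericVector times(n_frames), pe_frames(n_frames);
  NumericVector ke_mean(n_frames - 1), bond_mean(n_frames - 1);

  EnergyTerms et = compute_forces(x, f, top, pl, box, ks, r0, kappa, sigma2);
  times[0] = time0;
  pe_frames[0] = et.stretch + et.bend + et.pair;
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) frames[i + n * d] = x[3 * i + d];

  const double invbox = 1.0 / box;
  const size_t nb = top.bond_i.size();
  double ke_acc = 0.0, bond_acc = 0.0;
  int frame = 1, in_interval = 0;

  for (int step = 1; step <= n_steps; ++step) {
    // B
    const double hb = 0.5 * dt * acc_fac;
    for (int k = 0; k < 3 * n; ++k) v[k] += hb * f[k];
    // A
    for (int k = 0; k < 3 * n; ++k) x[k] += 0.5 * dt * v[k];
    // O
    rng.fill_gauss(g.data(), 3 * n);
    for (int k = 0; k < 3 * n; ++k) v[k] = c1 * v[k] + c2 * g[k];
    // A
    for (int k = 0; k < 3 * n; ++k) {
      x[k] += 0.5 * dt * v[k];
      x[k] -= box * std::floor(x[k] * invbox); // wrap into [0, box)
    }
    if (use_nlist && list_stale(pl, x, box, half_skin2)) {
      build_pair_list(pl, x, top, pp, box, skin, maxcut);
      ++n_rebuilds;
    }
    et = compute_forces(x, f, top, pl, box, ks, r0, kappa, sigma2);
    // B
    for (int k = 0; k < 3 * n; ++k) v[k] += hb * f[k];

    // running statistics over every step of the interval
    double v2 = 0.0;
    for (int k = 0; k < 3 * n; ++k) v2 += v[k] * v[k];
    ke_acc += kin_fac * v2;                // instantaneous kinetic temperature
    double bsum = 0.0;
    for (size_t b = 0; b < nb; ++b) {
      const int i = top.bond_i[b], j = top.bond_j[b];
      const double dx = min_image(x[3 * i] - x[3 * j], box, invbox);
      const double dy = min_image(x[3 * i + 1] - x[3 * j + 1], box, invbox);
      const double dz = min_image(x[3 * i + 2] - x[3 * j + 2], box, invbox);
      bsum += std::sqrt(dx * dx + dy * dy + dz * dz);
    }
    bond_acc += bsum / (double)nb;
    ++in_interval;

    if (step % report_every == 0) {
      if (!std::isfinite(x[0]) || !std::isfinite(v2)) {
        for (int i = 0; i < n; ++i)
          for (int d = 0; d < 3; ++d)
            if (!std::isfinite(x[3 * i + d]))
              stop("integration blew up: non-finite coordinate at bead %d", i + 1);
        stop("integration blew up: non-finite velocity");
      }
      const size_t off = (size_t)frame * 3 * n;
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) frames[off + i + n * d] = x[3 * i + d];
      times[frame] = time0 + (double)step * dt;
      pe_frames[frame] = et.stretch + et.bend + et.pair;
      ke_mean[frame - 1] = ke_acc / in_interval;
      bond_mean[frame - 1] = bond_acc / in_interval;
      ke_acc = 0.0; bond_acc = 0.0; in_interval = 0;
      ++frame;
    }
  }

  NumericMatrix fpos(n, 3), fvel(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      fpos(i, d) = x[3 * i + d];
      fvel(i, d) = v[3 * i + d];
    }

  return List::create(
      _["times"] = times, _["frames"] = frames, _["pe"] = pe_frames,
      _["ke_temp"] = ke_mean, _["bond_len"] = bond_mean,
      _["final_pos"] = fpos, _["final_vel"] = fvel,
      _["rng_state"] = rng_serialize(rng), _["n_rebuilds"] = n_rebuilds,
      _["final_pe"] = et.stretch + et.bend + et.pair);
}

// ---------------------------------------------------------------------------
// Contact counting and chain clustering
// ---------------------------------------------------------------------------

struct UnionFind {
  std::vector<int> p;
  UnionFind(int n) : p(n) { for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int a) { while (p[a] != a) a = p[a] = p[p[a]]; return a; }
  void unite(int a, int b) { p[find(a)] = find(b); }
};

// classify one inter-chain pair: 0 = neither, 1 = non-specific, 2 = specific
static inline int pair_class(int ra, int rb) {
  if (ra == 0 && rb == 0) return 2;
  if (ra == 1 || rb == 1 || ra == 3 || rb == 3) return 1;
  return 0;
}

// [[Rcpp::export]]
List cpp_contacts(NumericMatrix pos, IntegerVector role, IntegerVector chain,
                  double box, double cutoff) {
  const int n = pos.nrow();
  const double invbox = 1.0 / box, cut2 = cutoff * cutoff;
  int nchain = 0;
  for (int i = 0; i < n; ++i) nchain = std::max(nchain, chain[i] + 1);
  IntegerMatrix adj(nchain, nchain);
  int nsp = 0, nns = 0, nany = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (chain[i] == chain[j]) continue;
      double dx = min_image(pos(i, 0) - pos(j, 0), box, invbox);
      double dy = min_image(pos(i, 1) - pos(j, 1), box, invbox);
      double dz = min_image(pos(i, 2) - pos(j, 2), box, invbox);
      if (dx * dx + dy * dy + dz * dz >= cut2) continue;
      ++nany;
      adj(chain[i], chain[j]) = 1;
      adj(chain[j], chain[i]) = 1;
      const int cl = pair_class(role[i], role[j]);
      if (cl == 2) ++nsp; else if (cl == 1) ++nns;
    }
  }
  return List::create(_["n_sp_pairs"] = nsp, _["n_ns_pairs"] = nns,
                      _["n_any_pairs"] = nany, _["adjacency"] = adj);
}

// Per-frame contact series over a whole trajectory block.  Returns a matrix
// with columns: n_sp_pairs, n_ns_pairs, n_any_pairs, n_lc.
// [[Rcpp::export]]
NumericMatrix cpp_contact_series(NumericVector frames, IntegerVector role,
                                 IntegerVector chain, double box,
                                 double cutoff) {
  IntegerVector dim = frames.attr("dim");
  if (dim.size() != 3) stop("frames must be an N x 3 x F array");
  const int n = dim[0], nf = dim[2];
  if (dim[1] != 3) stop("frames must be an N x 3 x F array");
  const double invbox = 1.0 / box, cut2 = cutoff * cutoff;
  int nchain = 0;
  for (int i = 0; i < n; ++i) nchain = std::max(nchain, chain[i] + 1);

  NumericMatrix out(nf, 4);
  const double *fr = REAL(frames);
  for (int k = 0; k < nf; ++k) {
    const double *p = fr + (size_t)k * 3 * n;
    UnionFind uf(nchain);
    int nsp = 0, nns = 0, nany = 0;
    for (int i = 0; i < n; ++i) {
      const double xi = p[i], yi = p[i + n], zi = p[i + 2 * n];
      for (int j = i + 1; j < n; ++j) {
        if (chain[i] == chain[j]) continue;
        double dx = min_image(xi - p[j], box, invbox);
        double dy = min_image(yi - p[j + n], box, invbox);
        double dz = min_image(zi - p[j + 2 * n], box, invbox);
        if (dx * dx + dy * dy + dz * dz >= cut2) continue;
        ++nany;
        uf.unite(chain[i], chain[j]);
        const int cl = pair_class(role[i], role[j]);
        if (cl == 2) ++nsp; else if (cl == 1) ++nns;
      }
    }
    std::vector<int> size(nchain, 0);
    int nlc = 1;
    for (int c = 0; c < nchain; ++c) {
      const int r = uf.find(c);
      if (++size[r] > nlc) nlc = size[r];
    }
    out(k, 0) = nsp; out(k, 1) = nns; out(k, 2) = nany; out(k, 3) = nlc;
  }
  colnames(out) = CharacterVector::create("n_sp_pairs", "n_ns_pairs",
                                          "n_any_pairs", "n_lc");
  return out;
}
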