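// Analog Monte Carlo neutron/photon transport kernel.
//
// Geometry: axis-aligned boxes, z-axis cylinders and annuli, priority
// resolved, with an optional voxelized phantom block.  Neutron physics:
// 1/v capture + energy-independent elastic scattering, isotropic in the
// centre-of-mass frame, free-gas target motion below a cutoff energy.
// Photons: straight-line attenuation with energy-absorption deposition.
// Tallies: track-length fluence per voxel in 3 energy bands, per-channel
// capture-rate foldings, hydrogen-recoil kerma, photon fluence/deposition,
// analog per-voxel capture counts.  Statistics by history batching.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static const double E0_EV = 0.0253;   // 2200 m/s anchor energy
static const double NUDGE = 1e-6;     // boundary crossing push, cm
static const double TH_CUT = 0.5;     // thermal/epithermal cut, eV (cadmium)
static const double EPI_CUT = 1.0e4;  // epithermal/fast cut, eV

// hydrogen elastic cross section rolloff: sigma(E) = sigma0 / (1 + E/EC_H),
// ~20.5 b below ~10 keV falling to ~4 b at 1 MeV (free-proton behaviour);
// heavier nuclides keep their energy-independent value
static const double EC_H = 2.5e5;     // eV
static inline double h_scatter_factor(double E_eV) {
  return 1.0 / (1.0 + E_eV / EC_H);
}

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ seeded via splitmix64 (deterministic across platforms)
// ---------------------------------------------------------------------------
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() {  // (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_cache = false;
  double cache = 0.0;
  inline double normal() {
    if (have_cache) { have_cache = false; return cache; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), th = 6.283185307179586 * u2;
    cache = r * std::sin(th); have_cache = true;
    return r * std::cos(th);
  }
};

// ---------------------------------------------------------------------------
// Materials
// ---------------------------------------------------------------------------
struct Mat {
  std::vector<double> A, Nsc, Nss;  // mass, N*sigma0_capture, N*sigma_scatter
  std::vector<int> chan;            // 0 none, 1 B10, 2 Li6, 3 N14, 4 H(n,g)
  double Sc0 = 0.0;                 // sum N*sigma0_c  -> Sig_c(E)=Sc0*sqrt(E0/E)
  double SigS = 0.0;                // sum N*sigma_s (energy independent)
  double NHss = 0.0;                // hydrogen-only N*sigma_s (recoil kerma)
  double density = 0.0;
  std::vector<double> muE, mu;      // photon mu_en grid (MeV, cm^-1)
};

static std::vector<Mat> parse_mats(List mats) {
  std::vector<Mat> out;
  for (int i = 0; i < mats.size(); ++i) {
    List mm = mats[i];
    Mat m;
    NumericVector A = mm["A"], s0 = mm["s0"], ss = mm["ss"], N = mm["N"];
    IntegerVector ch = mm["chan"];
    for (int k = 0; k < A.size(); ++k) {
      m.A.push_back(A[k]);
      m.Nsc.push_back(N[k] * s0[k]);
      m.Nss.push_back(N[k] * ss[k]);
      m.chan.push_back(ch[k]);
      m.Sc0 += N[k] * s0[k];
      m.SigS += N[k] * ss[k];
      if (A[k] < 1.5) m.NHss += N[k] * ss[k];
    }
    m.density = as<double>(mm["density"]);
    NumericVector muE = mm["muenE"], mu = mm["muen"];
    m.muE = std::vector<double>(muE.begin(), muE.end());
    m.mu = std::vector<double>(mu.begin(), mu.end());
    out.push_back(m);
  }
  return out;
}

static inline double mu_at(const Mat& m, double E_MeV) {
  const std::vector<double>& xs = m.muE;
  const std::vector<double>& ys = m.mu;
  int n = (int)xs.size();
  if (n == 0) return 0.0;
  if (E_MeV <= xs[0]) return ys[0];
  if (E_MeV >= xs[n - 1]) return ys[n - 1];
  int j = 1;
  while (xs[j] < E_MeV) ++j;
  double lx0 = std::log(xs[j - 1]), lx1 = std::log(xs[j]);
  double f = (std::log(E_MeV) - lx0) / (lx1 - lx0);
  double ly = (1 - f) * std::log(std::max(ys[j - 1], 1e-300)) +
              f * std::log(std::max(ys[j], 1e-300));
  return std::exp(ly);
}

// ---------------------------------------------------------------------------
// Geometry
// ---------------------------------------------------------------------------
struct Region {
  int type;       // 0 box, 1 cylinder, 2 annulus (z-axis)
  double p[6];
  int mat;        // 1-based material index
  double prio;
};

struct Phantom {
  bool present = false;
  double box[6];
  int nx = 0, ny = 0, nz = 0;
  double ox = 0, oy = 0, oz = 0, dx = 0, dy = 0, dz = 0;
  const int* matidx = nullptr;      // per-voxel 1-based material
  const double* dens = nullptr;     // per-voxel density g/cm3
};

struct Scene {
  std::vector<Region> regs;
  double bbox[6];
  Phantom ph;
};

static Scene parse_scene(List sc) {
  Scene s;
  NumericMatrix R = sc["regions"];
  for (int i = 0; i < R.nrow(); ++i) {
    Region r;
    r.type = (int)R(i, 0);
    for (int k = 0; k < 6; ++k) r.p[k] = R(i, 1 + k);
    r.mat = (int)R(i, 7);
    r.prio = R(i, 8);
    s.regs.push_back(r);
  }
  NumericVector bb = sc["bbox"];
  for (int k = 0; k < 6; ++k) s.bbox[k] = bb[k];
  if (sc.containsElementNamed("phantom") && !Rf_isNull(sc["phantom"])) {
    List ph = sc["phantom"];
    s.ph.present = true;
    NumericVector box = ph["box"], org = ph["origin"], d = ph["voxsize"];
    IntegerVector dims = ph["dims"];
    for (int k = 0; k < 6; ++k) s.ph.box[k] = box[k];
    s.ph.ox = org[0]; s.ph.oy = org[1]; s.ph.oz = org[2];
    s.ph.dx = d[0]; s.ph.dy = d[1]; s.ph.dz = d[2];
    s.ph.nx = dims[0]; s.ph.ny = dims[1]; s.ph.nz = dims[2];
    IntegerVector mi = ph["matidx"];
    NumericVector de = ph["dens"];
    s.ph.matidx = INTEGER(mi);
    s.ph.dens = REAL(de);
  }
  return s;
}

static inline bool in_box(const double* b, double x, double y, double z) {
  return x >= b[0] && x <= b[1] && y >= b[2] && y <= b[3] &&
         z >= b[4] && z <= b[5];
}

static inline bool region_contains(const Region& r, double x, double y, double z) {
  switch (r.type) {
    case 0:
      return x >= r.p[0] && x <= r.p[1] && y >= r.p[2] && y <= r.p[3] &&
             z >= r.p[4] && z <= r.p[5];
    case 1: {
      double dx = x - r.p[0], dy = y - r.p[1];
      return z >= r.p[3] && z <= r.p[4] && dx * dx + dy * dy <= r.p[2] * r.p[2];
    }
    case 2: {
      double dx = x - r.p[4], dy = y - r.p[5];
      double rr = dx * dx + dy * dy;
      return z >= r.p[2] && z <= r.p[3] && rr >= r.p[0] * r.p[0] &&
             rr <= r.p[1] * r.p[1];
    }
  }
  return false;
}

// Material at a point: phantom voxel wins, else highest-priority region.
// Returns (matindex, voxel-linear-index or -1).  0 = outside bbox or hole.
static inline int locate_pt(const Scene& s, double x, double y, double z,
                            long* pvox = nullptr) {
  if (pvox) *pvox = -1;
  if (!in_box(s.bbox, x, y, z)) return 0;
  if (s.ph.present && in_box(s.ph.box, x, y, z)) {
    const Phantom& p = s.ph;
    int ix = (int)std::floor((x - p.ox) / p.dx);
    int iy = (int)std::floor((y - p.oy) / p.dy);
    int iz = (int)std::floor((z - p.oz) / p.dz);
    if (ix >= 0 && ix < p.nx && iy >= 0 && iy < p.ny && iz >= 0 && iz < p.nz) {
      long v = (long)ix + (long)p.nx * ((long)iy + (long)p.ny * (long)iz);
      if (pvox) *pvox = v;
      return p.matidx[v];
    }
  }
  int best = 0;
  double bp = -1e300;
  for (size_t i = 0; i < s.regs.size(); ++i) {
    if (region_contains(s.regs[i], x, y, z) && s.regs[i].prio > bp) {
      bp = s.regs[i].prio;
      best = s.regs[i].mat;
    }
  }
  return best;
}

// Candidate crossing parameters of a ray with one region's surfaces.
static void region_candidates(const Region& r, const double* o, const double* u,
                              std::vector<double>& ts) {
  auto plane = [&](int ax, double v) {
    if (std::fabs(u[ax]) > 1e-14) ts.push_back((v - o[ax]) / u[ax]);
  };
  auto quad = [&](double cx, double cy, double rad) {
    double px = o[0] - cx, py = o[1] - cy;
    double a = u[0] * u[0] + u[1] * u[1];
    double b = 2.0 * (px * u[0] + py * u[1]);
    double c = px * px + py * py - rad * rad;
    if (a < 1e-14) return;
    double disc = b * b - 4 * a * c;
    if (disc < 0) return;
    double sq = std::sqrt(disc);
    ts.push_back((-b - sq) / (2 * a));
    ts.push_back((-b + sq) / (2 * a));
  };
  switch (r.type) {
    case 0:
      plane(0, r.p[0]); plane(0, r.p[1]);
      plane(1, r.p[2]); plane(1, r.p[3]);
      plane(2, r.p[4]); plane(2, r.p[5]);
      break;
    case 1:
      quad(r.p[0], r.p[1], r.p[2]);
      plane(2, r.p[3]); plane(2, r.p[4]);
      break;
    case 2:
      quad(r.p[4], r.p[5], r.p[0]);
      quad(r.p[4], r.p[5], r.p[1]);
      plane(2, r.p[2]); plane(2, r.p[3]);
      break;
  }
}

// Exact distance along u to the nearest surface where some region's
// containment flips (or the bounding box is exited).
static double dist_regions(const Scene& s, const double* o, const double* u) {
  double best = 1e300;
  std::vector<double> ts;
  for (size_t i = 0; i < s.regs.size(); ++i) {
    ts.clear();
    region_candidates(s.regs[i], o, u, ts);
    for (double t : ts) {
      if (t <= 1e-9 || t >= best) continue;
      double eps = 1e-7 * (1.0 + std::fabs(t));
      bool a = region_contains(s.regs[i], o[0] + u[0] * (t - eps),
                               o[1] + u[1] * (t - eps), o[2] + u[2] * (t - eps));
      bool b = region_contains(s.regs[i], o[0] + u[0] * (t + eps),
                               o[1] + u[1] * (t + eps), o[2] + u[2] * (t + eps));
      if (a != b) best = t;
    }
  }
  // bounding box exit
  for (int ax = 0; ax < 3; ++ax) {
    if (std::fabs(u[ax]) < 1e-14) continue;
    for (int side = 0; side < 2; ++side) {
      double t = (s.bbox[2 * ax + side] - o[ax]) / u[ax];
      if (t > 1e-9 && t < best) best = t;
    }
  }
  // phantom block boundary
  if (s.ph.present) {
    for (int ax = 0; ax < 3; ++ax) {
      if (std::fabs(u[ax]) < 1e-14) continue;
      for (int side = 0; side < 2; ++side) {
        double t = (s.ph.box[2 * ax + side] - o[ax]) / u[ax];
        if (t <= 1e-9 || t >= best) continue;
        double eps = 1e-7 * (1.0 + std::fabs(t));
        double pa[3], pb[3];
        for (int k = 0; k < 3; ++k) {
          pa[k] = o[k] + u[k] * (t - eps);
          pb[k] = o[k] + u[k] * (t + eps);
        }
        if (in_box(s.ph.box, pa[0], pa[1], pa[2]) !=
            in_box(s.ph.box, pb[0], pb[1], pb[2]))
          best = t;
      }
    }
  }
  return best;
}

// distance to next phantom voxel face (call only when inside the block)
static inline double dist_voxel(const Phantom& p, const double* o,
                                const double* u) {
  double best = 1e300;
  double org[3] = {p.ox, p.oy, p.oz};
  double d[3] = {p.dx, p.dy, p.dz};
  for (int ax = 0; ax < 3; ++ax) {
    if (std::fabs(u[ax]) < 1e-14) continue;
    double rel = (o[ax] - org[ax]) / d[ax];
    double next = u[ax] > 0 ? (std::floor(rel) + 1.0) : (std::ceil(rel) - 1.0);
    double t = (org[ax] + next * d[ax] - o[ax]) / u[ax];
    if (t <= 1e-9) t = d[ax] / std::fabs(u[ax]);  // sitting on a face
    if (t < best) best = t;
  }
  return best;
}

// ---------------------------------------------------------------------------
// Tally mesh
// ---------------------------------------------------------------------------
struct Mesh {
  int nx = 0, ny = 0, nz = 0;
  double ox = 0, oy = 0, oz = 0, dx = 0, dy = 0, dz = 0;
  long nv = 0;
  double vol = 0.0;
};

static Mesh parse_mesh(List t) {
  Mesh m;
  NumericVector o = t["origin"], d = t["d"];
  IntegerVector n = t["dims"];
  m.ox = o[0]; m.oy = o[1]; m.oz = o[2];
  m.dx = d[0]; m.dy = d[1]; m.dz = d[2];
  m.nx = n[0]; m.ny = n[1]; m.nz = n[2];
  m.nv = (long)m.nx * m.ny * m.nz;
  m.vol = m.dx * m.dy * m.dz;
  return m;
}

// Walk the segment [pos, pos + t*u] across mesh voxels; call f(voxel, a, b)
// with a,b the parameter range (from segment start) spent in that voxel.
template <typename F>
static void mesh_walk(const Mesh& m, const double* pos, const double* u,
                      double t, F f) {
  double lo[3] = {m.ox, m.oy, m.oz};
  double hi[3] = {m.ox + m.nx * m.dx, m.oy + m.ny * m.dy, m.oz + m.nz * m.dz};
  double ta = 0.0, tb = t;
  for (int ax = 0; ax < 3; ++ax) {
    double o = pos[ax], d = u[ax];
    if (std::fabs(d) < 1e-14) {
      if (o < lo[ax] || o > hi[ax]) return;
    } else {
      double t0 = (lo[ax] - o) / d, t1 = (hi[ax] - o) / d;
      if (t0 > t1) std::swap(t0, t1);
      ta = std::max(ta, t0);
      tb = std::min(tb, t1);
    }
  }
  if (tb <= ta) return;
  double ds[3] = {m.dx, m.dy, m.dz};
  int n[3] = {m.nx, m.ny, m.nz};
  double pa[3];
  int ix[3];
  double tmax[3], tdel[3];
  int step[3];
  double tcur = ta;
  for (int ax = 0; ax < 3; ++ax) {
    pa[ax] = pos[ax] + u[ax] * (ta + 1e-12);
    int i = (int)std::floor((pa[ax] - lo[ax]) / ds[ax]);
    if (i < 0) i = 0;
    if (i > n[ax] - 1) i = n[ax] - 1;
    ix[ax] = i;
    if (u[ax] > 1e-14) {
      step[ax] = 1;
      tmax[ax] = ta + (lo[ax] + (i + 1) * ds[ax] - pa[ax]) / u[ax];
      tdel[ax] = ds[ax] / u[ax];
    } else if (u[ax] < -1e-14) {
      step[ax] = -1;
      tmax[ax] = ta + (lo[ax] + i * ds[ax] - pa[ax]) / u[ax];
      tdel[ax] = -ds[ax] / u[ax];
    } else {
      step[ax] = 0;
      tmax[ax] = 1e300;
      tdel[ax] = 1e300;
    }
  }
  int guard = 4 * (n[0] + n[1] + n[2]) + 8;
  while (tcur < tb - 1e-12 && guard-- > 0) {
    int ax = 0;
    if (tmax[1] < tmax[ax]) ax = 1;
    if (tmax[2] < tmax[ax]) ax = 2;
    double tnext = std::min(tmax[ax], tb);
    long v = (long)ix[0] + (long)n[0] * ((long)ix[1] + (long)n[1] * (long)ix[2]);
    if (tnext > tcur) f(v, tcur, tnext);
    tcur = tnext;
    if (tmax[ax] >= tb) break;
    ix[ax] += step[ax];
    if (ix[ax] < 0 || ix[ax] >= n[ax]) break;
    tmax[ax] += tdel[ax];
  }
}

static inline long mesh_voxel(const Mesh& m, double x, double y, double z) {
  int ix = (int)std::floor((x - m.ox) / m.dx);
  int iy = (int)std::floor((y - m.oy) / m.dy);
  int iz = (int)std::floor((z - m.oz) / m.dz);
  if (ix < 0 || ix >= m.nx || iy < 0 || iy >= m.ny || iz < 0 || iz >= m.nz)
    return -1;
  return (long)ix + (long)m.nx * ((long)iy + (long)m.ny * (long)iz);
}

// ---------------------------------------------------------------------------
// Source sampling
// ---------------------------------------------------------------------------
struct Source {
  std::vector<double> nb, ncum;  // neutron group bounds / cumulative intensity
  std::vector<double> gb, gcum;  // gamma
  double radius = 0, z0 = 0, m = 2.0, p_gamma = 0.0;
};

static Source parse_source(List s) {
  Source src;
  NumericVector nb = s["n_bounds"], ni = s["n_int"];
  src.nb = std::vector<double>(nb.begin(), nb.end());
  double c = 0;
  for (double v : ni) { c += v; src.ncum.push_back(c); }
  for (double& v : src.ncum) v /= c;
  if (!Rf_isNull(s["g_bounds"])) {
    NumericVector gb = s["g_bounds"], gi = s["g_int"];
    src.gb = std::vector<double>(gb.begin(), gb.end());
    double cg = 0;
    for (double v : gi) { cg += v; src.gcum.push_back(cg); }
    if (cg > 0) for (double& v : src.gcum) v /= cg;
  }
  src.radius = as<double>(s["radius"]);
  src.z0 = as<double>(s["z0"]);
  src.m = as<double>(s["m"]);
  src.p_gamma = as<double>(s["p_gamma"]);
  return src;
}

static inline double sample_group_E(const std::vector<double>& bounds,
                                    const std::vector<double>& cum, Rng& rng) {
  double u = rng.unif();
  int g = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
  if (g >= (int)cum.size()) g = (int)cum.size() - 1;
  double lo = bounds[g], hi = bounds[g + 1];
  return lo * std::pow(hi / lo, rng.unif());
}

struct Particle {
  int species;  // 0 neutron, 1 photon
  double x, y, z, ux, uy, uz, E, w;
};

static Particle sample_particle(const Source& s, Rng& rng) {
  Particle p;
  double r = s.radius * std::sqrt(rng.unif());
  double phi = 6.283185307179586 * rng.unif();
  p.x = r * std::cos(phi);
  p.y = r * std::sin(phi);
  p.z = s.z0;
  double mu;
  if (s.m < 0) mu = 1.0;  // pencil-beam limit
  else mu = std::pow(rng.unif(), 1.0 / (s.m + 1.0));
  double st = std::sqrt(std::max(0.0, 1.0 - mu * mu));
  double phi2 = 6.283185307179586 * rng.unif();
  p.ux = st * std::cos(phi2);
  p.uy = st * std::sin(phi2);
  p.uz = mu;
  bool gamma = (s.p_gamma > 0 && !s.gcum.empty() && rng.unif() < s.p_gamma);
  p.species = gamma ? 1 : 0;
  p.E = gamma ? sample_group_E(s.gb, s.gcum, rng)
              : sample_group_E(s.nb, s.ncum, rng);
  p.w = 1.0;
  return p;
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_source(List source, int n, double seed) {
  Source s = parse_source(source);
  Rng rng((uint64_t)seed);
  NumericMatrix out(n, 8);
  for (int i = 0; i < n; ++i) {
    Particle p = sample_particle(s, rng);
    out(i, 0) = p.species;
    out(i, 1) = p.x; out(i, 2) = p.y; out(i, 3) = p.z;
    out(i, 4) = p.ux; out(i, 5) = p.uy; out(i, 6) = p.uz;
    out(i, 7) = p.E;
  }
  colnames(out) = CharacterVector::create("species", "x", "y", "z",
                                          "ux", "uy", "uz", "energy");
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_locate(List scene, NumericMatrix pts) {
  Scene s = parse_scene(scene);
  int n = pts.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    if (!in_box(s.bbox, pts(i, 0), pts(i, 1), pts(i, 2))) out[i] = -1;
    else out[i] = locate_pt(s, pts(i, 0), pts(i, 1), pts(i, 2));
  }
  return out;
}

// [[Rcpp::export]]
double cpp_distance(List scene, NumericVector pos, NumericVector dir) {
  Scene s = parse_scene(scene);
  double o[3] = {pos[0], pos[1], pos[2]};
  double u[3] = {dir[0], dir[1], dir[2]};
  return dist_regions(s, o, u);
}

// ---------------------------------------------------------------------------
// Transport
// ---------------------------------------------------------------------------
struct Tallies {
  long nv;
  std::vector<double> nflux[3], nbuf[3], nsum2[3];
  std::vector<double> onev_sub, onev_epi, b10, n14, hk, pflux, pedep;
  std::vector<double> ccnt[5];
  double tl_cap = 0, an_cap = 0;  // per-batch scalars (mesh-restricted)
  explicit Tallies(long n) : nv(n) {
    for (int g = 0; g < 3; ++g) {
      nflux[g].assign(n, 0.0); nbuf[g].assign(n, 0.0); nsum2[g].assign(n, 0.0);
    }
    onev_sub.assign(n, 0.0); onev_epi.assign(n, 0.0);
    b10.assign(n, 0.0); n14.assign(n, 0.0); hk.assign(n, 0.0);
    pflux.assign(n, 0.0); pedep.assign(n, 0.0);
    for (int c = 1; c < 5; ++c) ccnt[c].assign(n, 0.0);
  }
};

struct RunPars {
  long n = 0;
  int nbatch = 20;
  bool photons = true;
  bool implicit_capture = false;
  double fg_cut = 1.0;       // free-gas treatment below this energy, eV
  double kT = 0.0253;        // eV
  double recoil_cut = 0.5;   // hydrogen-recoil kerma scored above this, eV
  double s0_b10 = 3837.0, s0_n14 = 1.83;
  double wmin = 0.01, wsurv = 0.1;
  long monitor = -1;
  double target_relerr = 0.0;
  uint64_t seed = 1;
};

struct Counters {
  double absorbed = 0, escaped = 0, lost = 0;
  double g_absorbed = 0, g_escaped = 0, secondary_photons = 0;
  double n_primaries = 0, g_primaries = 0;
};

static void transport_photon(const Scene& sc, const std::vector<Mat>& mats,
                             const Mesh& mesh, Tallies& tal, Counters& cnt,
                             double* pos, double* u, double E_eV, double w,
                             bool primary) {
  double E_MeV = E_eV * 1e-6;
  double w0 = w;
  int guard = 100000;
  while (guard-- > 0) {
    long pvox;
    int mi = locate_pt(sc, pos[0], pos[1], pos[2], &pvox);
    if (mi <= 0) { if (primary) cnt.g_escaped += 1; return; }
    const Mat& m = mats[mi - 1];
    double scale = 1.0;
    if (pvox >= 0 && sc.ph.present)
      scale = sc.ph.dens[pvox] / std::max(m.density, 1e-12);
    double mu = mu_at(m, E_MeV) * scale;
    double db = dist_regions(sc, pos, u);
    if (pvox >= 0) db = std::min(db, dist_voxel(sc.ph, pos, u));
    if (db > 1e9) { if (primary) cnt.g_escaped += 1; return; }
    // deposit along this single-material segment, voxel by voxel
    if (mu > 1e-12) {
      double wloc = w;
      mesh_walk(mesh, pos, u, db, [&](long v, double a, double b) {
        double fa = std::exp(-mu * a), fb = std::exp(-mu * b);
        tal.pedep[v] += w * E_MeV * (fa - fb);
        tal.pflux[v] += w * (fa - fb) / mu;
        (void)wloc;
      });
      w *= std::exp(-mu * db);
    } else {
      mesh_walk(mesh, pos, u, db, [&](long v, double a, double b) {
        tal.pflux[v] += w * (b - a);
      });
    }
    for (int k = 0; k < 3; ++k) pos[k] += u[k] * (db + NUDGE);
    if (w < 1e-4 * w0) { if (primary) cnt.g_absorbed += 1; return; }
  }
  if (primary) cnt.g_escaped += 1;
}

// isotropic unit vector
static inline void iso_dir(Rng& rng, double* u) {
  double z = 2.0 * rng.unif() - 1.0;
  double phi = 6.283185307179586 * rng.unif();
  double st = std::sqrt(std::max(0.0, 1.0 - z * z));
  u[0] = st * std::cos(phi); u[1] = st * std::sin(phi); u[2] = z;
}

// Elastic scatter with target of mass A; free-gas Maxwellian target motion
// when fg is true.  Velocities in sqrt(eV) units (u = sqrt(E)).
static void elastic_scatter(Rng& rng, double A, double kT, bool fg,
                            double& E, double* dir) {
  double un = std::sqrt(E);
  double vn[3] = {un * dir[0], un * dir[1], un * dir[2]};
  double vt[3] = {0, 0, 0};
  if (fg) {
    double sd = std::sqrt(kT / (2.0 * A));
    for (int it = 0; it < 1000; ++it) {
      for (int k = 0; k < 3; ++k) vt[k] = sd * rng.normal();
      double rel[3] = {vn[0] - vt[0], vn[1] - vt[1], vn[2] - vt[2]};
      double vr = std::sqrt(rel[0] * rel[0] + rel[1] * rel[1] + rel[2] * rel[2]);
      double vtm = std::sqrt(vt[0] * vt[0] + vt[1] * vt[1] + vt[2] * vt[2]);
      if (rng.unif() < vr / (un + vtm + 1e-12)) break;
      if (it == 999) { vt[0] = vt[1] = vt[2] = 0; }
    }
  }
  double cm[3], g[3];
  for (int k = 0; k < 3; ++k) cm[k] = (vn[k] + A * vt[k]) / (1.0 + A);
  for (int k = 0; k < 3; ++k) g[k] = vn[k] - cm[k];
  double gm = std::sqrt(g[0] * g[0] + g[1] * g[1] + g[2] * g[2]);
  double om[3];
  iso_dir(rng, om);
  double vnew[3];
  for (int k = 0; k < 3; ++k) vnew[k] = cm[k] + gm * om[k];
  double E2 = vnew[0] * vnew[0] + vnew[1] * vnew[1] + vnew[2] * vnew[2];
  E = std::max(E2, 1e-5);
  double sp = std::sqrt(E2);
  if (sp > 1e-12) {
    for (int k = 0; k < 3; ++k) dir[k] = vnew[k] / sp;
  }
}

// [[Rcpp::export]]
List cpp_transport(List source, List scene, List mats, List tally, List run) {
  Source src = parse_source(source);
  Scene sc = parse_scene(scene);
  std::vector<Mat> M = parse_mats(mats);
  Mesh mesh = parse_mesh(tally);
  RunPars rp;
  rp.n = (long)as<double>(run["n"]);
  rp.nbatch = as<int>(run["nbatch"]);
  rp.photons = as<bool>(run["photons"]);
  rp.implicit_capture = as<bool>(run["implicit"]);
  rp.fg_cut = as<double>(run["fg_cut"]);
  rp.kT = as<double>(run["kT"]);
  rp.recoil_cut = as<double>(run["recoil_cut"]);
  rp.s0_b10 = as<double>(run["s0_b10"]);
  rp.s0_n14 = as<double>(run["s0_n14"]);
  rp.monitor = (long)as<double>(run["monitor"]);
  rp.target_relerr = as<double>(run["target_relerr"]);
  rp.seed = (uint64_t)as<double>(run["seed"]);

  Tallies tal(mesh.nv);
  Counters cnt;
  Rng rng(rp.seed);

  int nb = std::max(1, rp.nbatch);
  long per_batch = std::max(1L, rp.n / nb);
  std::vector<double> tl_cap_b, an_cap_b, mon_b;
  long histories = 0;
  int batches_done = 0;

  for (int b = 0; b < nb; ++b) {
    tal.tl_cap = 0; tal.an_cap = 0;
    for (long h = 0; h < per_batch; ++h) {
      ++histories;
      Particle p = sample_particle(src, rng);
      double pos[3] = {p.x, p.y, p.z};
      double dir[3] = {p.ux, p.uy, p.uz};
      double E = p.E, w = p.w;
      if (p.species == 1) {
        cnt.g_primaries += 1;
        transport_photon(sc, M, mesh, tal, cnt, pos, dir, E, w, true);
        continue;
      }
      cnt.n_primaries += 1;
      bool alive = true;
      int guard = 1000000;
      while (alive && guard-- > 0) {
        long pvox;
        int mi = locate_pt(sc, pos[0], pos[1], pos[2], &pvox);
        if (mi <= 0) { cnt.escaped += w; alive = false; break; }
        const Mat& m = M[mi - 1];
        double scale = 1.0;
        if (pvox >= 0 && sc.ph.present)
          scale = sc.ph.dens[pvox] / std::max(m.density, 1e-12);
        double sq = std::sqrt(E0_EV / E);
        double fH = h_scatter_factor(E);
        double Sc = m.Sc0 * sq * scale;
        double Ss = (m.SigS - m.NHss + m.NHss * fH) * scale;
        double St = Sc + Ss;
        double db = dist_regions(sc, pos, dir);
        if (pvox >= 0) db = std::min(db, dist_voxel(sc.ph, pos, dir));
        double s = (St > 1e-11) ? -std::log(rng.unif()) / St : 1e300;
        double t = std::min(s, db);
        if (t > 1e9) { cnt.escaped += w; alive = false; break; }
        // --- score track-length tallies over [pos, pos + t*dir]
        int g = E < TH_CUT ? 0 : (E < EPI_CUT ? 1 : 2);
        double hk_c = (E >= rp.recoil_cut)
                          ? m.NHss * fH * scale * 0.5 * E * 1e-6 : 0.0;
        mesh_walk(mesh, pos, dir, t, [&](long v, double a, double bb) {
          double L = (bb - a) * w;
          tal.nbuf[g][v] += L;
          if (E < TH_CUT) tal.onev_sub[v] += L * sq;
          else tal.onev_epi[v] += L * sq;
          tal.b10[v] += L * rp.s0_b10 * sq;
          tal.n14[v] += L * rp.s0_n14 * sq;
          if (hk_c > 0) tal.hk[v] += L * hk_c;
          tal.tl_cap += L * Sc;
        });
        if (t >= db) {  // boundary crossing
          for (int k = 0; k < 3; ++k) pos[k] += dir[k] * (db + NUDGE);
          continue;
        }
        for (int k = 0; k < 3; ++k) pos[k] += dir[k] * t;
        // --- collision
        double Pc = Sc / St;
        if (!rp.implicit_capture) {
          if (rng.unif() < Pc) {
            // capture: choose nuclide by N*sigma0 share
            double x = rng.unif() * m.Sc0;
            double acc = 0; int ch = 0;
            for (size_t k = 0; k < m.Nsc.size(); ++k) {
              acc += m.Nsc[k];
              if (x <= acc) { ch = m.chan[k]; break; }
            }
            long v = mesh_voxel(mesh, pos[0], pos[1], pos[2]);
            if (v >= 0) {
              tal.an_cap += w;
              if (ch > 0) tal.ccnt[ch][v] += w;
            }
            cnt.absorbed += w;
            if (ch == 4 && rp.photons) {  // 1H(n,g): 2.223 MeV photon
              cnt.secondary_photons += 1;
              double gpos[3] = {pos[0], pos[1], pos[2]};
              double gd[3];
              iso_dir(rng, gd);
              transport_photon(sc, M, mesh, tal, cnt, gpos, gd, 2.223e6, w,
                               false);
            }
            alive = false;
            break;
          }
        } else {
          double wcap = w * Pc;
          long v = mesh_voxel(mesh, pos[0], pos[1], pos[2]);
          if (v >= 0) {
            tal.an_cap += wcap;
            for (size_t k = 0; k < m.Nsc.size(); ++k)
              if (m.chan[k] > 0)
                tal.ccnt[m.chan[k]][v] += wcap * m.Nsc[k] / m.Sc0;
          }
          cnt.absorbed += wcap;
          if (rp.photons && m.Sc0 > 0) {
            double fH = 0;
            for (size_t k = 0; k < m.Nsc.size(); ++k)
              if (m.chan[k] == 4) fH += m.Nsc[k] / m.Sc0;
            if (fH > 0) {
              cnt.secondary_photons += 1;
              double gpos[3] = {pos[0], pos[1], pos[2]};
              double gd[3];
              iso_dir(rng, gd);
              transport_photon(sc, M, mesh, tal, cnt, gpos, gd, 2.223e6,
                               wcap * fH, false);
            }
          }
          w *= (1.0 - Pc);
        }
        // elastic scatter: choose nuclide by N*sigma_s(E) share
        double SsMac = m.SigS - m.NHss + m.NHss * fH;
        if (SsMac > 1e-14) {
          double x = rng.unif() * SsMac;
          double acc = 0;
          double A = m.A.empty() ? 1.0 : m.A[0];
          for (size_t k = 0; k < m.Nss.size(); ++k) {
            acc += m.Nss[k] * (m.A[k] < 1.5 ? fH : 1.0);
            if (x <= acc) { A = m.A[k]; break; }
          }
          elastic_scatter(rng, A, rp.kT, E < rp.fg_cut, E, dir);
        }
        if (rp.implicit_capture && w < rp.wmin) {
          if (rng.unif() < w / rp.wsurv) w = rp.wsurv;
          else { cnt.lost += w; alive = false; }
        }
      }
    }
    // --- end of batch: fold buffers
    double mon = 0;
    for (int g = 0; g < 3; ++g) {
      double* buf = tal.nbuf[g].data();
      double* sm = tal.nflux[g].data();
      double* s2 = tal.nsum2[g].data();
      for (long v = 0; v < mesh.nv; ++v) {
        sm[v] += buf[v];
        s2[v] += buf[v] * buf[v];
        if (v == rp.monitor) mon += buf[v];
        buf[v] = 0.0;
      }
    }
    tl_cap_b.push_back(tal.tl_cap);
    an_cap_b.push_back(tal.an_cap);
    mon_b.push_back(mon);
    batches_done = b + 1;
    if (rp.target_relerr > 0 && batches_done >= 5 && rp.monitor >= 0) {
      double mtot = 0, m2 = 0;
      for (double v : mon_b) { mtot += v; m2 += v * v; }
      int k = batches_done;
      double var = (m2 - mtot * mtot / k) / std::max(1, k - 1);
      double re = mtot > 0 ? std::sqrt(var * k) / mtot : 1.0;
      if (re <= rp.target_relerr) break;
    }
    Rcpp::checkUserInterrupt();
  }

  double norm = 1.0 / ((double)histories * mesh.vol);
  auto finalize = [&](std::vector<double>& x) {
    NumericVector out(mesh.nv);
    for (long v = 0; v < mesh.nv; ++v) out[v] = x[v] * norm;
    return out;
  };
  List nf(3), re(3);
  for (int g = 0; g < 3; ++g) {
    NumericVector val(mesh.nv), rel(mesh.nv);
    int k = batches_done;
    for (long v = 0; v < mesh.nv; ++v) {
      double tot = tal.nflux[g][v];
      val[v] = tot * norm;
      if (tot > 0 && k > 1) {
        double var = (tal.nsum2[g][v] - tot * tot / k) / (k - 1);
        rel[v] = std::sqrt(std::max(0.0, var) * k) / tot;
      } else rel[v] = tot > 0 ? 0.0 : 1.0;
    }
    nf[g] = val;
    re[g] = rel;
  }
  List ccl(4);
  for (int c = 1; c < 5; ++c) ccl[c - 1] = finalize(tal.ccnt[c]);

  double mon_re = NA_REAL;
  {
    double mtot = 0, m2 = 0;
    for (double v : mon_b) { mtot += v; m2 += v * v; }
    int k = batches_done;
    if (k > 1 && mtot > 0) {
      double var = (m2 - mtot * mtot / k) / (k - 1);
      mon_re = std::sqrt(std::max(0.0, var) * k) / mtot;
    }
  }

  return List::create(
      _["nflux"] = nf, _["nflux_relerr"] = re,
      _["onev_sub"] = finalize(tal.onev_sub),
      _["onev_epi"] = finalize(tal.onev_epi),
      _["b10_fold"] = finalize(tal.b10), _["n14_fold"] = finalize(tal.n14),
      _["h_kerma"] = finalize(tal.hk),
      _["pflux"] = finalize(tal.pflux), _["pedep"] = finalize(tal.pedep),
      _["capture_counts"] = ccl,
      _["histories"] = (double)histories,
      _["absorbed"] = cnt.absorbed, _["escaped"] = cnt.escaped,
      _["lost"] = cnt.lost,
      _["n_primaries"] = cnt.n_primaries, _["g_primaries"] = cnt.g_primaries,
      _["g_absorbed"] = cnt.g_absorbed, _["g_escaped"] = cnt.g_escaped,
      _["secondary_photons"] = cnt.secondary_photons,
      _["tl_cap_batches"] = wrap(tl_cap_b),
      _["an_cap_batches"] = wrap(an_cap_b),
      _["monitor_batches"] = wrap(mon_b),
      _["monitor_relerr"] = mon_re,
      _["nbatches"] = batches_done);
}
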