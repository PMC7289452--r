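// Photon-packet Monte Carlo engine for layered hollow-organ geometries.
//
// Geometry is an implicit star-shaped cavity: the inner (void) surface is a
// radial graph r(u) over unit directions u about the origin, the wall and
// adipose layers are radial offsets of constant thickness.  Region lookup and
// ray-boundary intersection therefore reduce to evaluations of the scalar
// field d(p) = |p| - r(p/|p|) (negative in the void, 0 on the inner surface).
//
// Units: mm for all lengths, mm^-1 for interaction coefficients.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: splitmix64-seeded xoshiro256++, one independent stream per packet so
// results are reproducible under any batching of the packet loop.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  void seed(uint64_t seed_val) {
    uint64_t x = seed_val;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * 0x1.0p-53; }
};

// ---------------------------------------------------------------------------
// Geometry
// ---------------------------------------------------------------------------

enum ShapeKind { SPHERE = 0, ELLIPSOID = 1, SUPERELLIPSOID = 2, LOBULATED = 3 };

struct Geometry {
  int kind;
  double r0;            // sphere / lobulated base radius
  double ax, ay, az;    // ellipsoid / superellipsoid semi-axes
  double expo;          // superellipsoid exponent
  std::vector<double> bump_amp, bump_width; // lobulated bumps
  std::vector<double> bump_cx, bump_cy, bump_cz;
  double wall, adipose; // radial layer thicknesses

  // inner-surface radius along unit direction u
  double radius(double ux, double uy, double uz) const {
    switch (kind) {
    case SPHERE:
      return r0;
    case ELLIPSOID: {
      double q = (ux / ax) * (ux / ax) + (uy / ay) * (uy / ay) +
                 (uz / az) * (uz / az);
      return 1.0 / std::sqrt(q);
    }
    case SUPERELLIPSOID: {
      double q = std::pow(std::fabs(ux) / ax, expo) +
                 std::pow(std::fabs(uy) / ay, expo) +
                 std::pow(std::fabs(uz) / az, expo);
      return std::pow(q, -1.0 / expo);
    }
    default: { // LOBULATED: smooth radial bumps on a sphere
      double f = 1.0;
      for (size_t j = 0; j < bump_amp.size(); ++j) {
        double dp = ux * bump_cx[j] + uy * bump_cy[j] + uz * bump_cz[j];
        f += bump_amp[j] * std::exp(-(1.0 - dp) / bump_width[j]);
      }
      return r0 * f;
    }
    }
  }

  // signed radial field: <0 void, 0 inner surface, grows outward
  double dfield(double x, double y, double z) const {
    double rho = std::sqrt(x * x + y * y + z * z);
    if (rho < 1e-12) return -radius(0.0, 0.0, 1.0);
    return rho - radius(x / rho, y / rho, z / rho);
  }

  // 0 void, 1 wall, 2 adipose, 3 outside
  int region(double x, double y, double z) const {
    double d = dfield(x, y, z);
    if (d < 0.0) return 0;
    if (d < wall) return 1;
    if (d < wall + adipose) return 2;
    return 3;
  }

  // outward normal (direction of increasing d), by central differences
  void normal(double x, double y, double z, double *n) const {
    const double h = 1e-4;
    n[0] = dfield(x + h, y, z) - dfield(x - h, y, z);
    n[1] = dfield(x, y + h, z) - dfield(x, y - h, z);
    n[2] = dfield(x, y, z + h) - dfield(x, y, z - h);
    double nn = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
    for (int i = 0; i < 3; ++i) n[i] /= nn;
  }
};

static Geometry geometry_from_list(List g) {
  Geometry geom;
  geom.kind = as<int>(g["kind"]);
  geom.r0 = as<double>(g["r0"]);
  NumericVector axes = g["axes"];
  geom.ax = axes[0]; geom.ay = axes[1]; geom.az = axes[2];
  geom.expo = as<double>(g["exponent"]);
  NumericMatrix bumps = g["bumps"];
  for (int j = 0; j < bumps.nrow(); ++j) {
    geom.bump_amp.push_back(bumps(j, 0));
    geom.bump_width.push_back(bumps(j, 1));
    geom.bump_cx.push_back(bumps(j, 2));
    geom.bump_cy.push_back(bumps(j, 3));
    geom.bump_cz.push_back(bumps(j, 4));
  }
  geom.wall = as<double>(g["wall"]);
  geom.adipose = as<double>(g["adipose"]);
  return geom;
}

// quasi-uniform unit directions (golden-angle spiral lattice)
static void fib_dir(int i, int K, double *u) {
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  double z = 1.0 - (2.0 * i + 1.0) / K;
  double r = std::sqrt(std::max(0.0, 1.0 - z * z));
  double phi = ga * i;
  u[0] = r * std::cos(phi); u[1] = r * std::sin(phi); u[2] = z;
}

static inline int nearest_patch(const NumericMatrix &dirs, double ux,
                                double uy, double uz) {
  int best = 0;
  double bestdot = -2.0;
  for (int k = 0; k < dirs.nrow(); ++k) {
    double d = dirs(k, 0) * ux + dirs(k, 1) * uy + dirs(k, 2) * uz;
    if (d > bestdot) { bestdot = d; best = k; }
  }
  return best;
}

// ---------------------------------------------------------------------------
// Elementary physics, exported for unit-level checks and reused by the engine
// ---------------------------------------------------------------------------

static inline double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-12) return 2.0 * u - 1.0;
  double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - t * t) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

static inline double fresnel_R(double n1, double n2, double ci) {
  if (std::fabs(n1 - n2) < 1e-12) return 0.0;
  double st2 = (n1 / n2) * (n1 / n2) * (1.0 - ci * ci);
  if (st2 >= 1.0) return 1.0; // total internal reflection
  double ct = std::sqrt(1.0 - st2);
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// [[Rcpp::export]]
NumericVector hg_cos_cpp(double g, NumericVector u) {
  if (std::fabs(g) >= 1.0) stop("|g| must be < 1");
  NumericVector out(u.size());
  for (R_xlen_t i = 0; i < u.size(); ++i) out[i] = hg_cos(g, u[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector fresnel_cpp(double n1, double n2, NumericVector cosi) {
  NumericVector out(cosi.size());
  for (R_xlen_t i = 0; i < cosi.size(); ++i)
    out[i] = fresnel_R(n1, n2, std::fabs(cosi[i]));
  return out;
}

// [[Rcpp::export]]
NumericVector radius_cpp(List geom, NumericMatrix dirs) {
  Geometry g = geometry_from_list(geom);
  NumericVector out(dirs.nrow());
  for (int i = 0; i < dirs.nrow(); ++i)
    out[i] = g.radius(dirs(i, 0), dirs(i, 1), dirs(i, 2));
  return out;
}

// [[Rcpp::export]]
IntegerVector region_cpp(List geom, NumericMatrix pts) {
  Geometry g = geometry_from_list(geom);
  IntegerVector out(pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i)
    out[i] = g.region(pts(i, 0), pts(i, 1), pts(i, 2));
  return out;
}

// Numerically integrated void volume (mm^3) and inner-surface area (mm^2)
// over a K-point direction lattice.
// [[Rcpp::export]]
NumericVector geom_measures_cpp(List geom, int K) {
  Geometry g = geometry_from_list(geom);
  double dOmega = 4.0 * M_PI / K;
  double V = 0.0, A = 0.0;
  double u[3], n[3];
  for (int i = 0; i < K; ++i) {
    fib_dir(i, K, u);
    double R = g.radius(u[0], u[1], u[2]);
    V += R * R * R / 3.0 * dOmega;
    double p[3] = {R * u[0], R * u[1], R * u[2]};
    g.normal(p[0], p[1], p[2], n);
    double mu = n[0] * u[0] + n[1] * u[1] + n[2] * u[2];
    A += R * R / std::max(mu, 1e-6) * dOmega;
  }
  return NumericVector::create(_["volume"] = V, _["area"] = A);
}

// Per-patch area, surface centroid and mean outward normal for a spherical
// Voronoi partition of the inner surface induced by patch direction seeds.
// [[Rcpp::export]]
List patch_geometry_cpp(List geom, NumericMatrix patch_dirs, int K) {
  Geometry g = geometry_from_list(geom);
  int np = patch_dirs.nrow();
  NumericVector area(np);
  NumericMatrix cen(np, 3), nrm(np, 3);
  double dOmega = 4.0 * M_PI / K;
  double u[3], n[3];
  for (int i = 0; i < K; ++i) {
    fib_dir(i, K, u);
    double R = g.radius(u[0], u[1], u[2]);
    double p[3] = {R * u[0], R * u[1], R * u[2]};
    g.normal(p[0], p[1], p[2], n);
    double mu = n[0] * u[0] + n[1] * u[1] + n[2] * u[2];
    double dA = R * R / std::max(mu, 1e-6) * dOmega;
    int k = nearest_patch(patch_dirs, u[0], u[1], u[2]);
    area[k] += dA;
    for (int c = 0; c < 3; ++c) {
      cen(k, c) += p[c] * dA;
      nrm(k, c) += n[c] * dA;
    }
  }
  for (int k = 0; k < np; ++k) {
    for (int c = 0; c < 3; ++c) cen(k, c) /= std::max(area[k], 1e-300);
    double nn = std::sqrt(nrm(k, 0) * nrm(k, 0) + nrm(k, 1) * nrm(k, 1) +
                          nrm(k, 2) * nrm(k, 2));
    for (int c = 0; c < 3; ++c) nrm(k, c) /= std::max(nn, 1e-300);
    // project centroid onto the surface
    double cr = std::sqrt(cen(k, 0) * cen(k, 0) + cen(k, 1) * cen(k, 1) +
                          cen(k, 2) * cen(k, 2));
    if (cr > 1e-12) {
      double R = g.radius(cen(k, 0) / cr, cen(k, 1) / cr, cen(k, 2) / cr);
      for (int c = 0; c < 3; ++c) cen(k, c) *= R / cr;
    }
  }
  return List::create(_["areas"] = area, _["centers"] = cen,
                      _["normals"] = nrm);
}

// ---------------------------------------------------------------------------
// Direction utilities
// ---------------------------------------------------------------------------

static inline void spin(double *d, double cost, double phi) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double cosp = std::cos(phi), sinp = std::sin(phi);
  double ux = d[0], uy = d[1], uz = d[2];
  if (std::fabs(uz) > 0.99999) {
    d[0] = sint * cosp;
    d[1] = sint * sinp;
    d[2] = cost * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    d[0] = sint * (ux * uz * cosp - uy * sinp) / den + ux * cost;
    d[1] = sint * (uy * uz * cosp + ux * sinp) / den + uy * cost;
    d[2] = -sint * cosp * den + uz * cost;
  }
  double nn = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  d[0] /= nn; d[1] /= nn; d[2] /= nn;
}

static inline void iso_dir(Xoshiro &rng, double *d) {
  double z = 2.0 * rng.unif() - 1.0;
  double phi = 2.0 * M_PI * rng.unif();
  double r = std::sqrt(std::max(0.0, 1.0 - z * z));
  d[0] = r * std::cos(phi); d[1] = r * std::sin(phi); d[2] = z;
}

// ---------------------------------------------------------------------------
// Main transport kernel
// ---------------------------------------------------------------------------

// props: 3 x 4 matrix, rows = (void, wall, adipose), cols = (mu_a, mu_s, g, n)
// [[Rcpp::export]]
List mc_transport_cpp(List geom, NumericMatrix props, NumericVector src,
                      int n_packets, double seed, NumericMatrix patch_dirs,
                      double rt_thresh, double rt_surv, double max_path,
                      double h_max, double shell_width, int n_shells,
                      double n_exterior, bool record_crossings,
                      int max_crossings) {
  Geometry g = geometry_from_list(geom);
  int np = patch_dirs.nrow();
  std::vector<double> patch_w(np, 0.0), shells(n_shells, 0.0);
  double absorbed = 0.0, escaped = 0.0, killed = 0.0, boosted = 0.0;
  double lost_path = 0.0;
  long long n_cross = 0;

  std::vector<double> cr_patch, cr_w, cr_ci, cr_dx, cr_dy, cr_dz;
  bool cr_overflow = false;

  // conservative step bound inside the void: a sphere of radius r_min about
  // the origin is entirely void, so a packet at |p| < r_min may take a free
  // step of r_min - |p|
  double r_min = 1e300;
  {
    double u[3];
    for (int i = 0; i < 4096; ++i) {
      fib_dir(i, 4096, u);
      double R = g.radius(u[0], u[1], u[2]);
      if (R < r_min) r_min = R;
    }
    r_min *= 0.999;
  }

  const double mu_a[3] = {props(0, 0), props(1, 0), props(2, 0)};
  const double mu_s[3] = {props(0, 1), props(1, 1), props(2, 1)};
  const double gg[3] = {props(0, 2), props(1, 2), props(2, 2)};
  const double nn[4] = {props(0, 3), props(1, 3), props(2, 3), n_exterior};

  Xoshiro rng;
  for (int ip = 0; ip < n_packets; ++ip) {
    rng.seed(static_cast<uint64_t>(seed) * 0x100000001ULL +
             static_cast<uint64_t>(ip));
    double pos[3] = {src[0], src[1], src[2]};
    double dir[3];
    iso_dir(rng, dir);
    double w = 1.0, path = 0.0;
    int reg = 0;
    bool alive = true;

    while (alive) {
      double mt = mu_a[reg] + mu_s[reg];
      double s = (mt > 0.0) ? -std::log(1.0 - rng.unif()) / mt : 1e300;
      bool interact = false;

      // propagate distance s (or to the next boundary)
      while (s > 0.0) {
        double h = std::min(s, h_max);
        if (reg == 0) { // larger safe step deep inside the void
          double rho = std::sqrt(pos[0] * pos[0] + pos[1] * pos[1] +
                                 pos[2] * pos[2]);
          double safe = r_min - rho;
          if (safe > h) h = std::min(s, safe);
        }
        double np_[3] = {pos[0] + h * dir[0], pos[1] + h * dir[1],
                         pos[2] + h * dir[2]};
        int nreg = g.region(np_[0], np_[1], np_[2]);
        if (nreg == reg) {
          pos[0] = np_[0]; pos[1] = np_[1]; pos[2] = np_[2];
          s -= h; path += h;
          if (path > max_path) { // pathological long path: deposit locally
            absorbed += w; lost_path += w; alive = false; break;
          }
          if (s <= 0.0) interact = (mt > 0.0);
          continue;
        }
        // boundary inside (0, h]: bisect on region change
        double t0 = 0.0, t1 = h;
        for (int it = 0; it < 60 && (t1 - t0) > 1e-10; ++it) {
          double tm = 0.5 * (t0 + t1);
          double pm[3] = {pos[0] + tm * dir[0], pos[1] + tm * dir[1],
                          pos[2] + tm * dir[2]};
          if (g.region(pm[0], pm[1], pm[2]) == reg) t0 = tm;
          else { t1 = tm; nreg = g.region(pm[0], pm[1], pm[2]); }
        }
        double pb[3] = {pos[0] + t0 * dir[0], pos[1] + t0 * dir[1],
                        pos[2] + t0 * dir[2]};
        double pc[3] = {pos[0] + t1 * dir[0], pos[1] + t1 * dir[1],
                        pos[2] + t1 * dir[2]};
        path += t0;

        double m[3];
        g.normal(pb[0], pb[1], pb[2], m);
        double dn = dir[0] * m[0] + dir[1] * m[1] + dir[2] * m[2];
        double mu_sign = (dn >= 0.0) ? 1.0 : -1.0; // m_use = mu_sign * m
        double ci = std::fabs(dn);
        if (ci < 1e-9) ci = 1e-9;
        double n1 = nn[reg], n2 = nn[nreg];
        double R = fresnel_R(n1, n2, ci);

        if (rng.unif() < R) { // specular reflection, stay in region
          for (int c = 0; c < 3; ++c) dir[c] -= 2.0 * ci * mu_sign * m[c];
          double dl = std::sqrt(dir[0] * dir[0] + dir[1] * dir[1] +
                                dir[2] * dir[2]);
          for (int c = 0; c < 3; ++c) dir[c] /= dl;
          pos[0] = pb[0]; pos[1] = pb[1]; pos[2] = pb[2];
          break; // resample free path (memoryless)
        }

        // transmission: score void->wall crossings before updating direction
        if (reg == 0 && nreg == 1) {
          double rho = std::sqrt(pb[0] * pb[0] + pb[1] * pb[1] +
                                 pb[2] * pb[2]);
          int k = nearest_patch(patch_dirs, pb[0] / rho, pb[1] / rho,
                                pb[2] / rho);
          patch_w[k] += w;
          ++n_cross;
          if (record_crossings) {
            if ((int)cr_w.size() < max_crossings) {
              cr_patch.push_back(k + 1.0);
              cr_w.push_back(w);
              cr_ci.push_back(ci);
              cr_dx.push_back(dir[0]); cr_dy.push_back(dir[1]);
              cr_dz.push_back(dir[2]);
            } else cr_overflow = true;
          }
        }

        if (nreg == 3) { escaped += w; alive = false; break; }

        double eta = n1 / n2;
        double st2 = eta * eta * (1.0 - ci * ci);
        double ct = std::sqrt(std::max(0.0, 1.0 - st2));
        for (int c = 0; c < 3; ++c)
          dir[c] = eta * dir[c] + (ct - eta * ci) * mu_sign * m[c];
        double dl = std::sqrt(dir[0] * dir[0] + dir[1] * dir[1] +
                              dir[2] * dir[2]);
        for (int c = 0; c < 3; ++c) dir[c] /= dl;
        reg = nreg;
        pos[0] = pc[0]; pos[1] = pc[1]; pos[2] = pc[2];
        break; // resample free path in the new medium
      }
      if (!alive) break;
      if (!interact) continue;

      // absorption weighting at the interaction site
      mt = mu_a[reg] + mu_s[reg];
      double dep = w * mu_a[reg] / mt;
      absorbed += dep;
      if (reg == 1 || reg == 2) {
        double d = g.dfield(pos[0], pos[1], pos[2]);
        int sh = (int)std::floor(d / shell_width);
        if (sh >= 0 && sh < n_shells) shells[sh] += dep;
      }
      w -= dep;

      double cost = hg_cos(gg[reg], rng.unif());
      spin(dir, cost, 2.0 * M_PI * rng.unif());

      if (w < rt_thresh) { // Russian roulette
        if (rng.unif() < rt_surv) {
          boosted += w * (1.0 / rt_surv - 1.0);
          w /= rt_surv;
        } else {
          killed += w;
          alive = false;
        }
      }
    }
  }

  List out = List::create(
      _["patch_weight"] = NumericVector(patch_w.begin(), patch_w.end()),
      _["shell_weight"] = NumericVector(shells.begin(), shells.end()),
      _["absorbed"] = absorbed, _["escaped"] = escaped, _["killed"] = killed,
      _["boosted"] = boosted, _["lost_path"] = lost_path,
      _["n_crossings"] = (double)n_cross,
      _["crossings_overflow"] = cr_overflow);
  if (record_crossings) {
    int m = cr_w.size();
    NumericMatrix cr(m, 6);
    for (int i = 0; i < m; ++i) {
      cr(i, 0) = cr_patch[i]; cr(i, 1) = cr_w[i]; cr(i, 2) = cr_ci[i];
      cr(i, 3) = cr_dx[i]; cr(i, 4) = cr_dy[i]; cr(i, 5) = cr_dz[i];
    }
    out["crossings"] = cr;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Idealized integrating-sphere mode: spherical cavity, clear void, wall as a
// Lambertian diffuse reflector with reflectance rho.  Serves as an analytic
// oracle: total/primary irradiance = 1/(1-rho).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List mc_lambertian_cpp(double r0, NumericVector src, int n_packets,
                       double seed, NumericMatrix patch_dirs, double rho,
                       double rt_thresh, double rt_surv) {
  int np = patch_dirs.nrow();
  std::vector<double> total_w(np, 0.0), primary_w(np, 0.0);
  double absorbed = 0.0, killed = 0.0, boosted = 0.0;
  Xoshiro rng;
  for (int ip = 0; ip < n_packets; ++ip) {
    rng.seed(static_cast<uint64_t>(seed) * 0x100000001ULL + 0x9e3779b9ULL +
             static_cast<uint64_t>(ip));
    double pos[3] = {src[0], src[1], src[2]};
    double dir[3];
    iso_dir(rng, dir);
    double w = 1.0;
    bool first = true, alive = true;
    while (alive) {
      // ray-sphere intersection from inside
      double b = pos[0] * dir[0] + pos[1] * dir[1] + pos[2] * dir[2];
      double c = r0 * r0 -
                 (pos[0] * pos[0] + pos[1] * pos[1] + pos[2] * pos[2]);
      double t = -b + std::sqrt(b * b + c);
      for (int q = 0; q < 3; ++q) pos[q] += t * dir[q];
      int k = nearest_patch(patch_dirs, pos[0] / r0, pos[1] / r0,
                            pos[2] / r0);
      total_w[k] += w;
      if (first) { primary_w[k] += w; first = false; }
      absorbed += w * (1.0 - rho);
      w *= rho;
      if (w <= 0.0) break;
      if (w < rt_thresh) {
        if (rng.unif() < rt_surv) {
          boosted += w * (1.0 / rt_surv - 1.0);
          w /= rt_surv;
        } else { killed += w; alive = false; break; }
      }
      // Lambertian re-emission about the inward normal
      double nin[3] = {-pos[0] / r0, -pos[1] / r0, -pos[2] / r0};
      double z = std::sqrt(rng.unif());
      double phi = 2.0 * M_PI * rng.unif();
      double rxy = std::sqrt(std::max(0.0, 1.0 - z * z));
      // orthonormal frame about nin
      double a[3];
      if (std::fabs(nin[2]) < 0.9) { a[0] = 0; a[1] = 0; a[2] = 1; }
      else { a[0] = 1; a[1] = 0; a[2] = 0; }
      double e1[3] = {nin[1] * a[2] - nin[2] * a[1],
                      nin[2] * a[0] - nin[0] * a[2],
                      nin[0] * a[1] - nin[1] * a[0]};
      double e1n = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
      for (int q = 0; q < 3; ++q) e1[q] /= e1n;
      double e2[3] = {nin[1] * e1[2] - nin[2] * e1[1],
                      nin[2] * e1[0] - nin[0] * e1[2],
                      nin[0] * e1[1] - nin[1] * e1[0]};
      for (int q = 0; q < 3; ++q)
        dir[q] = rxy * std::cos(phi) * e1[q] + rxy * std::sin(phi) * e2[q] +
                 z * nin[q];
      // step slightly off the surface to avoid re-intersecting at t=0
      for (int q = 0; q < 3; ++q) pos[q] += 1e-9 * dir[q];
    }
  }
  return List::create(
      _["patch_weight"] = NumericVector(total_w.begin(), total_w.end()),
      _["primary_weight"] = NumericVector(primary_w.begin(), primary_w.end()),
      _["absorbed"] = absorbed, _["killed"] = killed, _["boosted"] = boosted);
}
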