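// Monte Carlo photon transport core: kerma-approximation tracking with a
// track-length estimator (TLE) on spherical (r, theta) shells around an
// analytically tracked encapsulated source, and an independent voxel engine
// (analog energy deposition or TLE) for slab phantoms.
//
// Units: lengths cm, energies MeV, linear attenuation 1/cm, mass
// coefficients cm2/g. Tallies are returned in raw estimator units
// (MeV*cm*cm2/g per bin, i.e. dose*volume per history before unit
// conversion); the R layer divides by bin volume and converts to Gy.
//
// RNG: MT19937 (std::mt19937) with an explicit uniform mapping so replay is
// bit-exact for a given seed across platforms.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

static const double MEC2 = 0.51099895;     // MeV
static const double TINY_LOG = -690.0;     // log(~1e-300), void attenuation

struct Rng {
  std::mt19937 gen;
  explicit Rng(uint32_t seed) : gen(seed) {}
  inline double u() { return (gen() + 0.5) * (1.0 / 4294967296.0); }
};

inline void iso_direction(Rng& rng, double* d) {
  double ct = 2.0 * rng.u() - 1.0;
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double ph = 6.283185307179586 * rng.u();
  d[0] = st * std::cos(ph);
  d[1] = st * std::sin(ph);
  d[2] = ct;
}

// rotate direction w by polar angle (cost) and uniform azimuth
inline void rotate_direction(double* w, double cost, Rng& rng) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double ph = 6.283185307179586 * rng.u();
  double cph = std::cos(ph), sph = std::sin(ph);
  double wx = w[0], wy = w[1], wz = w[2];
  double s2 = wx * wx + wy * wy;
  if (s2 > 1e-20) {
    double s = std::sqrt(s2);
    w[0] = cost * wx + sint * (wx * wz * cph - wy * sph) / s;
    w[1] = cost * wy + sint * (wy * wz * cph + wx * sph) / s;
    w[2] = cost * wz - sint * s * cph;
  } else {
    w[0] = sint * cph;
    w[1] = sint * sph;
    w[2] = (wz > 0 ? cost : -cost);
  }
  double n = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
  w[0] /= n; w[1] /= n; w[2] /= n;
}

// Klein-Nishina sampling (composition + rejection on the 1/eps and eps
// branches, GEANT4 style); returns scattered/incident energy ratio and the
// polar angle cosine, exact for a free electron at rest.
inline void compton_sample(double E, Rng& rng, double& eps, double& cost) {
  double a = E / MEC2;
  double e0 = 1.0 / (1.0 + 2.0 * a);
  double a1 = -std::log(e0);
  double a2 = 0.5 * (1.0 - e0 * e0);
  double sint2, greject;
  do {
    if (rng.u() * (a1 + a2) < a1)
      eps = std::exp(-a1 * rng.u());
    else
      eps = std::sqrt(e0 * e0 + (1.0 - e0 * e0) * rng.u());
    double t = (1.0 - eps) / (a * eps);
    sint2 = t * (2.0 - t);
    greject = 1.0 - eps * sint2 / (1.0 + eps * eps);
  } while (rng.u() > greject);
  cost = 1.0 - (1.0 - eps) / (a * eps);
}

// ---------------------------------------------------------------------------
// material tables (shared log-energy grid)

struct MatTables {
  std::vector<double> logE;
  std::vector<double> logMu;    // nE x nmat, log linear attenuation (1/cm)
  std::vector<double> logMuen;  // nE x nmat, log mu_en/rho (cm2/g)
  std::vector<double> pcomp;    // nE x nmat
  std::vector<int> isVoid;      // nmat
  std::vector<double> density;  // nmat, g/cm3
  int nE = 0, nmat = 0;

  void init(NumericVector logE_, NumericMatrix logMu_, NumericMatrix logMuen_,
            NumericMatrix pcomp_, IntegerVector isVoid_, NumericVector dens_) {
    nE = logE_.size();
    nmat = logMu_.ncol();
    logE.assign(logE_.begin(), logE_.end());
    logMu.resize((size_t)nE * nmat);
    logMuen.resize((size_t)nE * nmat);
    pcomp.resize((size_t)nE * nmat);
    for (int i = 0; i < nE; ++i)
      for (int m = 0; m < nmat; ++m) {
        logMu[(size_t)i * nmat + m] = logMu_(i, m);
        logMuen[(size_t)i * nmat + m] = logMuen_(i, m);
        pcomp[(size_t)i * nmat + m] = pcomp_(i, m);
      }
    isVoid.assign(isVoid_.begin(), isVoid_.end());
    density.assign(dens_.begin(), dens_.end());
  }
  inline void locate(double E, int& i, double& f) const {
    double le = std::log(E);
    if (le <= logE[0]) { i = 0; f = 0.0; return; }
    if (le >= logE[nE - 1]) { i = nE - 2; f = 1.0; return; }
    int lo = int(std::upper_bound(logE.begin(), logE.end(), le) -
                 logE.begin()) - 1;
    i = lo;
    f = (le - logE[lo]) / (logE[lo + 1] - logE[lo]);
  }
  inline double mu(int m, int i, double f) const {
    if (isVoid[m]) return 0.0;
    return std::exp(logMu[(size_t)i * nmat + m] * (1.0 - f) +
                    logMu[(size_t)(i + 1) * nmat + m] * f);
  }
  inline double muen_rho(int m, int i, double f) const {
    return std::exp(logMuen[(size_t)i * nmat + m] * (1.0 - f) +
                    logMuen[(size_t)(i + 1) * nmat + m] * f);
  }
  inline double p_compton(int m, int i, double f) const {
    return pcomp[(size_t)i * nmat + m] * (1.0 - f) +
           pcomp[(size_t)(i + 1) * nmat + m] * f;
  }
};

// ---------------------------------------------------------------------------
// encapsulated source geometry (analytic surfaces, source local frame)

struct SrcGeom {
  bool present = false;
  double r_core, z_core, r_cav, z_cav, r_out, z_cap_bot, tip_h, r_tip,
      z_wire_bot;
  double slope, z_tip, c0, bound_r;

  void init(NumericVector p) {
    present = p.size() > 0;
    if (!present) return;
    r_core = p[0]; z_core = p[1]; r_cav = p[2]; z_cav = p[3];
    r_out = p[4]; z_cap_bot = p[5]; tip_h = p[6]; r_tip = p[7];
    z_wire_bot = p[8];
    slope = (r_out - r_tip) / tip_h;
    z_tip = z_cav + tip_h;
    c0 = r_out + slope * z_cav;
    bound_r = std::sqrt(r_out * r_out +
                        std::max(z_tip * z_tip, z_wire_bot * z_wire_bot)) +
              1e-6;
  }
  // region ids: 0 core, 1 cavity, 2 capsule, 3 wire, 4 medium
  inline int region(double x, double y, double z) const {
    if (!present) return 4;
    double rho2 = x * x + y * y;
    if (std::fabs(z) <= z_core && rho2 <= r_core * r_core) return 0;
    if (std::fabs(z) <= z_cav && rho2 <= r_cav * r_cav) return 1;
    if (z >= z_cap_bot && z <= z_cav && rho2 <= r_out * r_out) return 2;
    if (z > z_cav && z <= z_tip) {
      double r = r_out - slope * (z - z_cav);
      if (rho2 <= r * r) return 2;
    }
    if (z >= z_wire_bot && z < z_cap_bot && rho2 <= r_out * r_out) return 3;
    return 4;
  }
  // all surface crossings of p + t*d for t in (eps, tmax)
  int roots(const double* p, const double* d, double tmax, double* ts) const {
    int n = 0;
    const double eps = 1e-9;
    double a2 = d[0] * d[0] + d[1] * d[1];
    double bq = p[0] * d[0] + p[1] * d[1];
    double rr[3] = {r_core, r_cav, r_out};
    for (int k = 0; k < 3; ++k) {
      if (a2 < 1e-20) continue;
      double c = p[0] * p[0] + p[1] * p[1] - rr[k] * rr[k];
      double disc = bq * bq - a2 * c;
      if (disc <= 0) continue;
      double sq = std::sqrt(disc);
      double t1 = (-bq - sq) / a2, t2 = (-bq + sq) / a2;
      if (t1 > eps && t1 < tmax) ts[n++] = t1;
      if (t2 > eps && t2 < tmax) ts[n++] = t2;
    }
    double zz[7] = {-z_core, z_core, -z_cav, z_cav, z_cap_bot, z_tip,
                    z_wire_bot};
    if (std::fabs(d[2]) > 1e-20)
      for (int k = 0; k < 7; ++k) {
        double t = (zz[k] - p[2]) / d[2];
        if (t > eps && t < tmax) ts[n++] = t;
      }
    // frustum cone: rho^2 = (c0 - slope*z)^2
    {
      double A = a2 - slope * slope * d[2] * d[2];
      double B = 2.0 * (bq - slope * slope * p[2] * d[2] +
                        c0 * slope * d[2]);
      double C = p[0] * p[0] + p[1] * p[1] -
                 slope * slope * p[2] * p[2] + 2.0 * c0 * slope * p[2] -
                 c0 * c0;
      if (std::fabs(A) > 1e-20) {
        double disc = B * B - 4.0 * A * C;
        if (disc > 0) {
          double sq = std::sqrt(disc);
          double t1 = (-B - sq) / (2.0 * A), t2 = (-B + sq) / (2.0 * A);
          if (t1 > eps && t1 < tmax) ts[n++] = t1;
          if (t2 > eps && t2 < tmax) ts[n++] = t2;
        }
      } else if (std::fabs(B) > 1e-20) {
        double t = -C / B;
        if (t > eps && t < tmax) ts[n++] = t;
      }
    }
    return n;
  }
};

// minimum distance from the origin to segment p + t*d, t in [ta, tb]
inline double seg_min_dist(const double* p, const double* d, double ta,
                           double tb) {
  double tca = -(p[0] * d[0] + p[1] * d[1] + p[2] * d[2]);
  if (tca < ta) tca = ta;
  if (tca > tb) tca = tb;
  double x = p[0] + tca * d[0], y = p[1] + tca * d[1], z = p[2] + tca * d[2];
  return std::sqrt(x * x + y * y + z * z);
}

// ---------------------------------------------------------------------------
// shell tally helper

struct ShellTally {
  std::vector<double> rE;     // nr+1 ascending radii
  std::vector<double> cosE;   // ntheta+1 interior cosines (descending)
  std::vector<double> thE;    // theta edges in degrees, ascending
  int nr = 0, nth = 0;
  std::vector<double> acc, sum, sumsq;
  std::vector<int> touched;

  void init(NumericVector rEdges, NumericVector thetaEdges) {
    rE.assign(rEdges.begin(), rEdges.end());
    thE.assign(thetaEdges.begin(), thetaEdges.end());
    nr = rE.size() - 1;
    nth = thE.size() - 1;
    cosE.resize(thE.size());
    for (size_t k = 0; k < thE.size(); ++k)
      cosE[k] = std::cos(thE[k] * 0.017453292519943295);
    acc.assign((size_t)nr * nth, 0.0);
    sum.assign((size_t)nr * nth, 0.0);
    sumsq.assign((size_t)nr * nth, 0.0);
  }
  inline int bin(double r, double theta_deg) const {
    if (r < rE[0] || r >= rE[nr]) return -1;
    if (theta_deg < thE[0] || theta_deg >= thE[nth]) return -1;
    int ir = 0, it = 0;
    while (ir < nr - 1 && r >= rE[ir + 1]) ++ir;
    while (it < nth - 1 && theta_deg >= thE[it + 1]) ++it;
    return ir * nth + it;
  }
  inline void add(int b, double v) {
    if (b < 0) return;
    if (acc[b] == 0.0) touched.push_back(b);
    acc[b] += v;
  }
  inline void end_history() {
    for (int b : touched) {
      sum[b] += acc[b];
      sumsq[b] += acc[b] * acc[b];
      acc[b] = 0.0;
    }
    touched.clear();
  }
  // score E * muen * chord over segment [ta, tb] of ray p + t*d
  void score(const double* p, const double* d, double ta, double tb,
             double weightE) {
    double tcrit[256];
    int n = 0;
    tcrit[n++] = ta;
    tcrit[n++] = tb;
    const double eps = 1e-12;
    // sphere crossings
    double bq = p[0] * d[0] + p[1] * d[1] + p[2] * d[2];
    double pp = p[0] * p[0] + p[1] * p[1] + p[2] * p[2];
    for (int k = 0; k <= nr && n < 250; ++k) {
      double disc = bq * bq - (pp - rE[k] * rE[k]);
      if (disc <= 0) continue;
      double sq = std::sqrt(disc);
      double t1 = -bq - sq, t2 = -bq + sq;
      if (t1 > ta + eps && t1 < tb - eps) tcrit[n++] = t1;
      if (t2 > ta + eps && t2 < tb - eps) tcrit[n++] = t2;
    }
    // theta cone crossings: z^2 = c^2 (x^2+y^2+z^2)
    for (int k = 0; k <= nth && n < 250; ++k) {
      double c2 = cosE[k] * cosE[k];
      if (c2 >= 1.0 - 1e-12) continue;
      double A = d[2] * d[2] - c2;
      double B = 2.0 * (p[2] * d[2] - c2 * bq);
      double C = p[2] * p[2] - c2 * pp;
      if (std::fabs(A) > 1e-20) {
        double disc = B * B - 4.0 * A * C;
        if (disc <= 0) continue;
        double sq = std::sqrt(disc);
        double t1 = (-B - sq) / (2.0 * A), t2 = (-B + sq) / (2.0 * A);
        if (t1 > ta + eps && t1 < tb - eps) tcrit[n++] = t1;
        if (t2 > ta + eps && t2 < tb - eps) tcrit[n++] = t2;
      } else if (std::fabs(B) > 1e-20) {
        double t = -C / B;
        if (t > ta + eps && t < tb - eps) tcrit[n++] = t;
      }
    }
    std::sort(tcrit, tcrit + n);
    for (int k = 0; k + 1 < n; ++k) {
      double len = tcrit[k + 1] - tcrit[k];
      if (len <= 0) continue;
      double tm = 0.5 * (tcrit[k] + tcrit[k + 1]);
      double x = p[0] + tm * d[0], y = p[1] + tm * d[1],
             z = p[2] + tm * d[2];
      double r = std::sqrt(x * x + y * y + z * z);
      double th = std::acos(std::min(1.0, std::max(-1.0, z / r))) *
                  57.29577951308232;
      add(bin(r, th), weightE * len);
    }
  }
};

inline int sample_line(const std::vector<double>& cdf, double u) {
  return int(std::lower_bound(cdf.begin(), cdf.end(), u) - cdf.begin());
}

// ---------------------------------------------------------------------------
// exported samplers

// [[Rcpp::export]]
NumericMatrix cpp_sample_decay(int n, int seed, NumericVector specE,
                               NumericVector specCdf, NumericVector geom) {
  Rng rng((uint32_t)seed);
  std::vector<double> cdf(specCdf.begin(), specCdf.end());
  bool point = geom.size() == 0;
  double r_core = point ? 0.0 : geom[0];
  double z_core = point ? 0.0 : geom[1];
  NumericMatrix out(n, 8);
  for (int i = 0; i < n; ++i) {
    double x = 0, y = 0, z = 0;
    if (!point) {
      double r = r_core * std::sqrt(rng.u());
      double ph = 6.283185307179586 * rng.u();
      x = r * std::cos(ph);
      y = r * std::sin(ph);
      z = (2.0 * rng.u() - 1.0) * z_core;
    }
    double d[3];
    iso_direction(rng, d);
    int li = sample_line(cdf, rng.u());
    out(i, 0) = x; out(i, 1) = y; out(i, 2) = z;
    out(i, 3) = d[0]; out(i, 4) = d[1]; out(i, 5) = d[2];
    out(i, 6) = specE[li]; out(i, 7) = 1.0;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_compton(int n, double energy, int seed) {
  Rng rng((uint32_t)seed);
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double eps, cost;
    compton_sample(energy, rng, eps, cost);
    out(i, 0) = eps * energy;
    out(i, 1) = cost;
  }
  return out;
}

// ---------------------------------------------------------------------------
// exact voxel traversal (Amanatides-Woo); used by the voxel engine and
// exported for verification against analytic box intersections

// [[Rcpp::export]]
List cpp_trace_voxels(NumericVector start, NumericVector dir,
                      IntegerVector dims, NumericVector spacing,
                      NumericVector origin) {
  double p[3] = {start[0], start[1], start[2]};
  double d[3] = {dir[0], dir[1], dir[2]};
  double nrm = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  for (int k = 0; k < 3; ++k) d[k] /= nrm;
  int nx[3] = {dims[0], dims[1], dims[2]};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double o[3] = {origin[0], origin[1], origin[2]};

  // clip ray to the grid box (slab method)
  double t0 = 0.0, t1 = 1e300;
  for (int k = 0; k < 3; ++k) {
    double lo = o[k], hi = o[k] + nx[k] * sp[k];
    if (std::fabs(d[k]) < 1e-20) {
      if (p[k] < lo || p[k] > hi) return List::create(
          Named("ijk") = IntegerMatrix(0, 3),
          Named("chord") = NumericVector(0));
    } else {
      double ta = (lo - p[k]) / d[k], tb = (hi - p[k]) / d[k];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta);
      t1 = std::min(t1, tb);
    }
  }
  if (t1 <= t0) return List::create(Named("ijk") = IntegerMatrix(0, 3),
                                    Named("chord") = NumericVector(0));
  std::vector<int> iv[3];
  std::vector<double> chords;
  double pe[3];
  double tcur = t0 + 1e-12;
  for (int k = 0; k < 3; ++k) pe[k] = p[k] + tcur * d[k];
  int ix[3], step[3];
  double tmaxv[3], tdelta[3];
  for (int k = 0; k < 3; ++k) {
    ix[k] = (int)std::floor((pe[k] - o[k]) / sp[k]);
    if (ix[k] < 0) ix[k] = 0;
    if (ix[k] >= nx[k]) ix[k] = nx[k] - 1;
    if (d[k] > 1e-20) {
      step[k] = 1;
      tmaxv[k] = ((o[k] + (ix[k] + 1) * sp[k]) - p[k]) / d[k];
      tdelta[k] = sp[k] / d[k];
    } else if (d[k] < -1e-20) {
      step[k] = -1;
      tmaxv[k] = ((o[k] + ix[k] * sp[k]) - p[k]) / d[k];
      tdelta[k] = -sp[k] / d[k];
    } else {
      step[k] = 0;
      tmaxv[k] = 1e300;
      tdelta[k] = 1e300;
    }
  }
  tcur = t0;
  while (tcur < t1 - 1e-12) {
    int kmin = 0;
    if (tmaxv[1] < tmaxv[kmin]) kmin = 1;
    if (tmaxv[2] < tmaxv[kmin]) kmin = 2;
    double tnext = std::min(tmaxv[kmin], t1);
    double len = tnext - tcur;
    if (len > 0) {
      iv[0].push_back(ix[0] + 1);
      iv[1].push_back(ix[1] + 1);
      iv[2].push_back(ix[2] + 1);
      chords.push_back(len);
    }
    tcur = tnext;
    if (tmaxv[kmin] >= t1) break;
    ix[kmin] += step[kmin];
    if (ix[kmin] < 0 || ix[kmin] >= nx[kmin]) break;
    tmaxv[kmin] += tdelta[kmin];
  }
  IntegerMatrix ijk(chords.size(), 3);
  NumericVector ch(chords.size());
  for (size_t i = 0; i < chords.size(); ++i) {
    ijk(i, 0) = iv[0][i];
    ijk(i, 1) = iv[1][i];
    ijk(i, 2) = iv[2][i];
    ch[i] = chords[i];
  }
  return List::create(Named("ijk") = ijk, Named("chord") = ch);
}

// ---------------------------------------------------------------------------
// source-in-sphere engine (TLE on (r, theta) shells)

// [[Rcpp::export]]
List cpp_sphere_run(double n_hist, int seed, NumericVector specE,
                    NumericVector specCdf, NumericVector geomParams,
                    double sphereR, NumericVector rEdges,
                    NumericVector thetaEdges, IntegerVector regionMat,
                    NumericVector logE, NumericMatrix logMu,
                    NumericMatrix logMuen, NumericMatrix pcomp,
                    IntegerVector isVoid, NumericVector density,
                    int scoringMat, int mediumMat, double cut,
                    bool primariesOnly) {
  Rng rng((uint32_t)seed);
  MatTables tab;
  tab.init(logE, logMu, logMuen, pcomp, isVoid, density);
  SrcGeom geom;
  geom.init(geomParams);
  ShellTally tally;
  tally.init(rEdges, thetaEdges);
  std::vector<double> cdf(specCdf.begin(), specCdf.end());
  double maxRscore = tally.rE[tally.nr];
  bool mediumVoid = tab.isVoid[mediumMat] != 0;
  double rhoMed = tab.density[mediumMat];
  double rcore = geom.present ? geom.r_core : 0.0;
  double zcore = geom.present ? geom.z_core : 0.0;
  long long n = (long long)n_hist;
  double n_below_cut = 0.0;

  for (long long h = 0; h < n; ++h) {
    if ((h & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    // emission
    double p[3] = {0.0, 0.0, 0.0};
    if (geom.present) {
      double r = rcore * std::sqrt(rng.u());
      double ph = 6.283185307179586 * rng.u();
      p[0] = r * std::cos(ph);
      p[1] = r * std::sin(ph);
      p[2] = (2.0 * rng.u() - 1.0) * zcore;
    }
    double d[3];
    iso_direction(rng, d);
    int li = sample_line(cdf, rng.u());
    double E = specE[li];
    if (E < cut) { n_below_cut += 1.0; continue; }  // counted, not transported

    bool alive = true;
    while (alive) {
      int ei; double ef;
      tab.locate(E, ei, ef);
      // distance to sphere exit
      double bq = p[0] * d[0] + p[1] * d[1] + p[2] * d[2];
      double pp = p[0] * p[0] + p[1] * p[1] + p[2] * p[2];
      double disc = bq * bq - (pp - sphereR * sphereR);
      if (disc <= 0) break;  // outside sphere already (should not happen)
      double tmax = -bq + std::sqrt(disc);
      if (tmax <= 1e-12) break;

      // partition by source surfaces
      double ts[40];
      int nroot = 0;
      if (geom.present && seg_min_dist(p, d, 0.0, tmax) < geom.bound_r)
        nroot = geom.roots(p, d, tmax, ts);
      ts[nroot++] = tmax;
      std::sort(ts, ts + nroot);

      double tau = -std::log(rng.u());
      double tprev = 0.0;
      bool interacted = false;
      double tint = 0.0;
      int matInt = -1, regInt = -1;
      for (int k = 0; k < nroot && !interacted; ++k) {
        double tk = ts[k];
        if (tk <= tprev + 1e-12) { tprev = std::max(tprev, tk); continue; }
        double tm = 0.5 * (tprev + tk);
        int reg = geom.region(p[0] + tm * d[0], p[1] + tm * d[1],
                              p[2] + tm * d[2]);
        int m = regionMat[reg];
        double mu = tab.mu(m, ei, ef);
        double segEnd = tk;
        double len = tk - tprev;
        if (mu > 0 && mu * len >= tau) {
          segEnd = tprev + tau / mu;
          interacted = true;
          tint = segEnd;
          matInt = m;
          regInt = reg;
        } else if (mu > 0) {
          tau -= mu * len;
        }
        // TLE scoring on medium segments near the shells
        if (reg == 4 && segEnd > tprev &&
            seg_min_dist(p, d, tprev, segEnd) <= maxRscore) {
          double muen = tab.muen_rho(scoringMat, ei, ef);
          tally.score(p, d, tprev, segEnd, E * muen);
        }
        tprev = tk;
      }
      if (!interacted) break;  // escaped through the sphere surface

      for (int k = 0; k < 3; ++k) p[k] += tint * d[k];
      if (primariesOnly) break;
      double pc = tab.p_compton(matInt, ei, ef);
      if (rng.u() < pc) {
        double eps, cost;
        compton_sample(E, rng, eps, cost);
        E *= eps;
        rotate_direction(d, cost, rng);
        if (E < cut) {
          // terminate with local deposition (analog bookkeeping of the
          // sub-cut remnant; negligible transport range at <10 keV)
          if (regInt == 4 && !mediumVoid) {
            double r = std::sqrt(p[0] * p[0] + p[1] * p[1] + p[2] * p[2]);
            double th = std::acos(std::min(1.0, std::max(-1.0, p[2] /
                std::max(r, 1e-12)))) * 57.29577951308232;
            tally.add(tally.bin(r, th), E / rhoMed);
          }
          alive = false;
        }
      } else {
        alive = false;  // photoabsorption: kerma already scored by TLE
      }
    }
    tally.end_history();
  }
  NumericVector sum(tally.sum.begin(), tally.sum.end());
  NumericVector sumsq(tally.sumsq.begin(), tally.sumsq.end());
  return List::create(Named("sum") = sum, Named("sumsq") = sumsq,
                      Named("n") = (double)n,
                      Named("n_below_cut") = n_below_cut);
}

// ---------------------------------------------------------------------------
// voxel phantom engine (analog deposition or TLE; optional Woodcock tracking)

// [[Rcpp::export]]
List cpp_voxel_run(double n_hist, int seed, IntegerVector matIndex,
                   IntegerVector dims, NumericVector spacing,
                   NumericVector origin, NumericVector logE,
                   NumericMatrix logMu, NumericMatrix logMuen,
                   NumericMatrix pcomp, IntegerVector isVoid,
                   NumericVector density, NumericVector specE,
                   NumericVector specCdf, NumericVector srcCenter,
                   NumericVector srcFrame, NumericVector geomParams,
                   double cut, int scoring, bool primariesOnly,
                   bool woodcock) {
  Rng rng((uint32_t)seed);
  MatTables tab;
  tab.init(logE, logMu, logMuen, pcomp, isVoid, density);
  SrcGeom geom;
  geom.init(geomParams);
  std::vector<double> cdf(specCdf.begin(), specCdf.end());
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t nvox = (size_t)nx * ny * nz;
  const double sp[3] = {spacing[0], spacing[1], spacing[2]};
  const double o[3] = {origin[0], origin[1], origin[2]};
  const double hi[3] = {o[0] + nx * sp[0], o[1] + ny * sp[1],
                        o[2] + nz * sp[2]};
  // source local frame axes in global coordinates (columns u1 u2 u3)
  double U[9];
  for (int k = 0; k < 9; ++k) U[k] = srcFrame[k];
  const double ctr[3] = {srcCenter[0], srcCenter[1], srcCenter[2]};
  const bool tle = scoring == 1;

  std::vector<double> sum(nvox, 0.0), sumsq(nvox, 0.0), hacc(nvox, 0.0);
  std::vector<long long> lasth(nvox, -1);
  std::vector<size_t> touched;
  double emitted = 0.0, deposited = 0.0, escaped = 0.0, void_banked = 0.0;
  long long n = (long long)n_hist;

  // per-history contribution
  auto contrib = [&](size_t v, double val, long long h) {
    if (lasth[v] != h) {
      lasth[v] = h;
      touched.push_back(v);
    }
    hacc[v] += val;
  };

  double rcore = geom.present ? geom.r_core : 0.0;
  double zcore = geom.present ? geom.z_core : 0.0;

  for (long long h = 0; h < n; ++h) {
    if ((h & 0x3FFFF) == 0) Rcpp::checkUserInterrupt();
    // emission in the source local frame -> global
    double lx = 0, ly = 0, lz = 0;
    if (geom.present) {
      double r = rcore * std::sqrt(rng.u());
      double ph = 6.283185307179586 * rng.u();
      lx = r * std::cos(ph);
      ly = r * std::sin(ph);
      lz = (2.0 * rng.u() - 1.0) * zcore;
    }
    double p[3];
    for (int k = 0; k < 3; ++k)
      p[k] = ctr[k] + U[k] * lx + U[3 + k] * ly + U[6 + k] * lz;
    double d[3];
    iso_direction(rng, d);
    int li = sample_line(cdf, rng.u());
    double E = specE[li];
    emitted += E;

    auto voxel_at = [&](const double* q, int* ix) -> bool {
      for (int k = 0; k < 3; ++k) {
        ix[k] = (int)std::floor((q[k] - o[k]) / sp[k]);
        if (ix[k] < 0 || ix[k] >= dims[k]) return false;
      }
      return true;
    };
    auto deposit = [&](const double* q, double e) {
      int ix[3];
      if (!voxel_at(q, ix)) { escaped += e; return; }
      size_t v = (size_t)ix[0] + nx * ((size_t)ix[1] + (size_t)ny * ix[2]);
      int m = matIndex[v] - 1;
      if (tab.isVoid[m]) { void_banked += e; return; }
      deposited += e;
      if (!tle) contrib(v, e, h);
      else contrib(v, e / tab.density[m], h);  // energy -> dose*V (MeV cm3/g)
    };

    if (E < cut) {  // dropped at sampling; deposit at emission point
      deposit(p, E);
      // still counted as a history
      for (size_t v : touched) {
        sum[v] += hacc[v];
        sumsq[v] += hacc[v] * hacc[v];
        hacc[v] = 0.0;
      }
      touched.clear();
      continue;
    }

    bool alive = true;
    while (alive) {
      int ei; double ef;
      tab.locate(E, ei, ef);

      if (woodcock) {
        // delta tracking: exponential flights with the majorant
        double mumax = 0.0;
        for (int m = 0; m < tab.nmat; ++m)
          mumax = std::max(mumax, tab.mu(m, ei, ef));
        bool real = false;
        int mcur = -1;
        size_t vcur = 0;
        while (!real) {
          double s = -std::log(rng.u()) / mumax;
          for (int k = 0; k < 3; ++k) p[k] += s * d[k];
          int ix[3];
          if (!voxel_at(p, ix)) { escaped += E; alive = false; break; }
          vcur = (size_t)ix[0] + nx * ((size_t)ix[1] + (size_t)ny * ix[2]);
          mcur = matIndex[vcur] - 1;
          double mu = tab.mu(mcur, ei, ef);
          if (rng.u() < mu / mumax) real = true;
        }
        if (!alive) break;
        // interaction at p in voxel vcur
        double pc = tab.p_compton(mcur, ei, ef);
        if (rng.u() < pc) {
          double eps, cost;
          compton_sample(E, rng, eps, cost);
          double Enew = E * eps;
          if (!tle) { deposited += E - Enew; contrib(vcur, E - Enew, h); }
          E = Enew;
          rotate_direction(d, cost, rng);
          if (primariesOnly) { escaped += E; break; }
          if (E < cut) { deposit(p, E); break; }
        } else {
          if (!tle) { deposited += E; contrib(vcur, E, h); }
          alive = false;
        }
        if (primariesOnly) break;
        continue;
      }

      // ray-traced voxel traversal with chord-wise optical depth
      // clip to grid
      double t1 = 1e300;
      bool inside = true;
      int ix[3];
      for (int k = 0; k < 3; ++k) {
        if (std::fabs(d[k]) > 1e-20) {
          double ta = (o[k] - p[k]) / d[k], tb = (hi[k] - p[k]) / d[k];
          if (ta > tb) std::swap(ta, tb);
          t1 = std::min(t1, tb);
        }
        ix[k] = (int)std::floor((p[k] - o[k]) / sp[k]);
        if (ix[k] < 0 || ix[k] >= dims[k]) inside = false;
      }
      if (!inside) { escaped += E; break; }
      int step[3];
      double tmaxv[3], tdelta[3];
      for (int k = 0; k < 3; ++k) {
        if (d[k] > 1e-20) {
          step[k] = 1;
          tmaxv[k] = ((o[k] + (ix[k] + 1) * sp[k]) - p[k]) / d[k];
          tdelta[k] = sp[k] / d[k];
        } else if (d[k] < -1e-20) {
          step[k] = -1;
          tmaxv[k] = ((o[k] + ix[k] * sp[k]) - p[k]) / d[k];
          tdelta[k] = -sp[k] / d[k];
        } else {
          step[k] = 0;
          tmaxv[k] = 1e300;
          tdelta[k] = 1e300;
        }
      }
      double tau = -std::log(rng.u());
      double tcur = 0.0;
      bool interacted = false;
      double tint = 0.0;
      size_t vint = 0;
      int mint = -1;
      while (tcur < t1 - 1e-12) {
        int kmin = 0;
        if (tmaxv[1] < tmaxv[kmin]) kmin = 1;
        if (tmaxv[2] < tmaxv[kmin]) kmin = 2;
        double tnext = std::min(tmaxv[kmin], t1);
        size_t v = (size_t)ix[0] + nx * ((size_t)ix[1] + (size_t)ny * ix[2]);
        int m = matIndex[v] - 1;
        double mu = tab.mu(m, ei, ef);
        double len = tnext - tcur;
        double segEnd = tnext;
        if (mu > 0 && mu * len >= tau) {
          segEnd = tcur + tau / mu;
          interacted = true;
          tint = segEnd;
          vint = v;
          mint = m;
        } else if (mu > 0) {
          tau -= mu * len;
        }
        if (tle && !tab.isVoid[m] && segEnd > tcur) {
          double muen = tab.muen_rho(m, ei, ef);
          contrib(v, E * muen * (segEnd - tcur), h);
        }
        if (interacted) break;
        tcur = tnext;
        if (tmaxv[kmin] >= t1) break;
        ix[kmin] += step[kmin];
        if (ix[kmin] < 0 || ix[kmin] >= dims[kmin]) break;
        tmaxv[kmin] += tdelta[kmin];
      }
      if (!interacted) { escaped += E; break; }
      for (int k = 0; k < 3; ++k) p[k] += tint * d[k];
      if (primariesOnly) { escaped += E; break; }
      double pc = tab.p_compton(mint, ei, ef);
      if (rng.u() < pc) {
        double eps, cost;
        compton_sample(E, rng, eps, cost);
        double Enew = E * eps;
        if (!tle) { deposited += E - Enew; contrib(vint, E - Enew, h); }
        E = Enew;
        rotate_direction(d, cost, rng);
        if (E < cut) {
          if (!tle) { deposited += E; contrib(vint, E, h); }
          else contrib(vint, E / tab.density[mint], h);
          alive = false;
        }
      } else {
        if (!tle) { deposited += E; contrib(vint, E, h); }
        alive = false;
      }
    }
    for (size_t v : touched) {
      sum[v] += hacc[v];
      sumsq[v] += hacc[v] * hacc[v];
      hacc[v] = 0.0;
    }
    touched.clear();
  }
  return List::create(Named("sum") = NumericVector(sum.begin(), sum.end()),
                      Named("sumsq") = NumericVector(sumsq.begin(),
                                                     sumsq.end()),
                      Named("n") = (double)n, Named("emitted") = emitted,
                      Named("deposited") = deposited,
                      Named("escaped") = escaped,
                      Named("void_banked") = void_banked);
}
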