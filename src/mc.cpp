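// Layered Monte Carlo photon transport with weighted direct fluorescence
// emission, MCML-style: step sampling by optical depth, Henyey-Greenstein
// scattering, continuous absorption weighting, survival roulette with an
// explicit roulette ledger so every run conserves energy exactly, and a
// fibre source/detector with NA-limited cosine launch, NA-limited
// detection and a perfectly reflecting ferrule annulus.
//
// The RNG is counter-based in spirit: each photon gets its own xoshiro256++
// stream keyed by (seed, photon index) through splitmix64, so results are
// reproducible and independent of execution order.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct RNG {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  RNG(uint64_t seed, uint64_t stream) {
    uint64_t x = seed ^ (stream * 0x632BE59BD9B4E019ULL + 0xD1B54A32D192ED03ULL);
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  // uniform in (0,1)
  double unif() { return ((next() >> 11) + 1) * (1.0 / 9007199254740993.0); }
};

const double W_THRESHOLD = 1e-4;   // roulette weight threshold
const double P_SURVIVE   = 0.1;    // roulette survival probability

struct Props {             // one wavelength's optical properties per layer
  std::vector<double> mua, mus, g, zb; // zb: layer boundaries, zb[0]=0
  double ztot;
  int nl;
};

struct Geom {
  double r_fib, na_t, r_ferrule, n_rel; // na_t = NA/n_tissue; n_rel = n_tissue
};

struct Ledger {
  double detected = 0, escaped = 0, transmitted = 0, roulette = 0;
  std::vector<double> absorbed;
};

struct Spawn { double x, y, z, w; int layer; };

inline int find_layer(const Props &p, double z) {
  for (int i = 0; i < p.nl - 1; ++i) if (z < p.zb[i + 1]) return i;
  return p.nl - 1;
}

inline double fresnel_R(double n_rel, double cos_i) {
  // unpolarized reflectance, tissue (n_rel) -> air (1)
  double sin_i = std::sqrt(std::max(0.0, 1.0 - cos_i * cos_i));
  double sin_t = n_rel * sin_i;
  if (sin_t >= 1.0) return 1.0;
  double cos_t = std::sqrt(1.0 - sin_t * sin_t);
  double rs = (n_rel * cos_i - cos_t) / (n_rel * cos_i + cos_t);
  double rp = (n_rel * cos_t - cos_i) / (n_rel * cos_t + cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

inline void hg_scatter(double g, RNG &rng, double &ux, double &uy, double &uz) {
  double cost;
  double u = rng.unif();
  if (std::fabs(g) < 1e-9) {
    cost = 2.0 * u - 1.0;
  } else {
    double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
    cost = (1.0 + g * g - t * t) / (2.0 * g);
  }
  if (cost > 1) cost = 1;
  if (cost < -1) cost = -1;
  double sint = std::sqrt(1.0 - cost * cost);
  double phi = 2.0 * M_PI * rng.unif();
  double cosp = std::cos(phi), sinp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = sint * cosp; uy = sint * sinp; uz = cost * (uz >= 0 ? 1 : -1);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = sint * (ux * uz * cosp - uy * sinp) / den + ux * cost;
    double ny = sint * (uy * uz * cosp + ux * sinp) / den + uy * cost;
    double nz = -sint * cosp * den + uz * cost;
    ux = nx; uy = ny; uz = nz;
  }
  double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= norm; uy /= norm; uz /= norm;
}

// Transport one photon through the stack. Spawns (fluorescence seeds) are
// collected when `spawns` is non-null and gamma_eff[layer] > 0; each spawn
// carries weight dw * gamma / spawn_prob with thinning probability
// spawn_prob (unbiased).
void transport(double x, double y, double z, double ux, double uy, double uz,
               double w, const Props &p, const Geom &gm, RNG &rng,
               Ledger &led, std::vector<Spawn> *spawns,
               const std::vector<double> *gamma_eff, double spawn_prob,
               std::vector<double> *depth_hist, double depth_max) {
  int layer = find_layer(p, z);
  int ndep = depth_hist ? (int)depth_hist->size() : 0;
  for (int guard = 0; guard < 2000000; ++guard) {
    double S = -std::log(rng.unif());   // optical depth to next interaction
    bool interact = false;
    while (!interact) {
      double mut = p.mua[layer] + p.mus[layer];
      double zb_lo = p.zb[layer], zb_hi = p.zb[layer + 1];
      double db;
      if (uz > 1e-12)       db = (zb_hi - z) / uz;
      else if (uz < -1e-12) db = (zb_lo - z) / uz;
      else                  db = 1e30;
      if (mut <= 0.0) {
        if (db >= 1e29) { led.escaped += w; return; } // horizontal in vacuum
      } else if (db * mut >= S) {
        double s = S / mut;
        x += ux * s; y += uy * s; z += uz * s;
        interact = true;
        break;
      }
      // cross boundary
      x += ux * db; y += uy * db; z += uz * db;
      if (mut > 0.0) S -= db * mut;
      if (uz > 0) {
        z = zb_hi;
        if (layer == p.nl - 1 || z >= p.ztot - 1e-15) {
          if (layer == p.nl - 1) { led.transmitted += w; return; }
        }
        ++layer;
        if (layer > p.nl - 1) { led.transmitted += w; return; }
      } else {
        z = zb_lo;
        if (layer == 0) {
          // top surface
          double rho = std::sqrt(x * x + y * y);
          double cos_i = -uz;
          double sin_i = std::sqrt(std::max(0.0, 1.0 - cos_i * cos_i));
          if (rho <= gm.r_fib) {
            if (sin_i <= gm.na_t) { led.detected += w; return; }
            led.escaped += w; return;  // hits fibre face outside NA: lost
          }
          if (rho <= gm.r_ferrule) { uz = -uz; continue; } // perfect mirror
          double R = fresnel_R(gm.n_rel, cos_i);
          led.escaped += w * (1.0 - R);
          w *= R;
          uz = -uz;
          if (w <= 0) return;
          continue;
        }
        --layer;
      }
    }
    // interaction: deposit, maybe spawn, scatter, roulette
    double mut = p.mua[layer] + p.mus[layer];
    double dw = w * p.mua[layer] / mut;
    if (dw > 0) {
      led.absorbed[layer] += dw;
      if (ndep > 0) {
        int b = (int)(z / depth_max * ndep);
        if (b >= 0 && b < ndep) (*depth_hist)[b] += dw;
      }
      if (spawns && (*gamma_eff)[layer] > 0.0 && rng.unif() < spawn_prob) {
        Spawn sp;
        sp.x = x; sp.y = y; sp.z = z;
        sp.w = dw * (*gamma_eff)[layer] / spawn_prob;
        sp.layer = layer;
        spawns->push_back(sp);
      }
      w -= dw;
    }
    if (w <= 0) return;
    hg_scatter(p.g[layer], rng, ux, uy, uz);
    if (w < W_THRESHOLD) {
      if (rng.unif() < P_SURVIVE) {
        led.roulette -= w * (1.0 / P_SURVIVE - 1.0);
        w /= P_SURVIVE;
      } else {
        led.roulette += w;
        return;
      }
    }
  }
  // guard tripped (pathological input); account weight to keep the ledger
  led.escaped += w;
}

Props props_from(const NumericMatrix &layers, int off) {
  // off = 1 for excitation columns, 4 for emission columns
  Props p;
  p.nl = layers.nrow();
  p.zb.push_back(0.0);
  for (int i = 0; i < p.nl; ++i) {
    p.mua.push_back(layers(i, off));
    p.mus.push_back(layers(i, off + 1));
    p.g.push_back(layers(i, off + 2));
    p.zb.push_back(p.zb.back() + layers(i, 0));
  }
  p.ztot = p.zb.back();
  return p;
}

} // namespace

// layers: matrix with columns
//   0 thickness_mm, 1 mua_exc, 2 mus_exc, 3 g_exc,
//   4 mua_em, 5 mus_em, 6 g_em, 7 frac_auto, 8 frac_znpp, 9 gamma
// [[Rcpp::export(name = ".mc_run_cpp")]]
List mc_run_cpp(NumericMatrix layers, double r_fib_mm, double na,
                double n_tissue, double r_ferrule_mm, int n_photons,
                double seed, bool fluorescence, double spawn_prob,
                int n_depth_bins, double depth_max_mm) {
  Props pe = props_from(layers, 1);
  Props pm = props_from(layers, 4);
  if (pe.ztot <= 0) stop("layer stack has zero total thickness");
  Geom gm;
  gm.r_fib = r_fib_mm;
  gm.na_t = na / n_tissue;
  gm.r_ferrule = r_ferrule_mm;
  gm.n_rel = n_tissue;
  int nl = pe.nl;
  std::vector<double> fa(nl), fz(nl), gamma_eff(nl);
  for (int i = 0; i < nl; ++i) {
    fa[i] = layers(i, 7);
    fz[i] = layers(i, 8);
    gamma_eff[i] = layers(i, 9) * ((fa[i] + fz[i]) > 0 ? 1.0 : 0.0);
  }
  double sin_max = na / n_tissue;   // launch cone, index-matched probe face

  Ledger exc; exc.absorbed.assign(nl, 0.0);
  std::vector<double> depth_hist;
  if (n_depth_bins > 0) depth_hist.assign(n_depth_bins, 0.0);

  // fluorescence tallies per class (0 = autofluorescence, 1 = ZnPP)
  double gen[2] = {0, 0}, fdet_tot[2] = {0, 0}, fabs[2] = {0, 0},
         fesc[2] = {0, 0}, ftra[2] = {0, 0}, frou[2] = {0, 0};
  NumericMatrix fdet(nl, 2);

  std::vector<Spawn> spawns;
  for (int i = 0; i < n_photons; ++i) {
    RNG rng((uint64_t)seed, (uint64_t)i);
    // launch: uniform over fibre face, cosine-weighted within NA cone
    double rho = gm.r_fib * std::sqrt(rng.unif());
    double phi = 2.0 * M_PI * rng.unif();
    double x = rho * std::cos(phi), y = rho * std::sin(phi);
    double s2 = rng.unif() * sin_max * sin_max;   // sin^2(theta) uniform
    double uzl = std::sqrt(1.0 - s2);
    double psi = 2.0 * M_PI * rng.unif();
    double sint = std::sqrt(s2);
    double ux = sint * std::cos(psi), uy = sint * std::sin(psi);

    spawns.clear();
    transport(x, y, 0.0, ux, uy, uzl, 1.0, pe, gm, rng, exc,
              fluorescence ? &spawns : nullptr, &gamma_eff, spawn_prob,
              n_depth_bins > 0 ? &depth_hist : nullptr, depth_max_mm);

    for (size_t k = 0; k < spawns.size(); ++k) {
      const Spawn &sp = spawns[k];
      double f[2] = {fa[sp.layer], fz[sp.layer]};
      for (int c = 0; c < 2; ++c) gen[c] += sp.w * f[c];
      // isotropic emission
      double cz = 2.0 * rng.unif() - 1.0;
      double sz = std::sqrt(std::max(0.0, 1.0 - cz * cz));
      double ph = 2.0 * M_PI * rng.unif();
      Ledger fl; fl.absorbed.assign(nl, 0.0);
      transport(sp.x, sp.y, sp.z, sz * std::cos(ph), sz * std::sin(ph), cz,
                sp.w, pm, gm, rng, fl, nullptr, nullptr, 0.0, nullptr, 0.0);
      double atot = 0;
      for (int l = 0; l < nl; ++l) atot += fl.absorbed[l];
      for (int c = 0; c < 2; ++c) {
        fdet(sp.layer, c) += fl.detected * f[c];
        fdet_tot[c] += fl.detected * f[c];
        fabs[c] += atot * f[c];
        fesc[c] += fl.escaped * f[c];
        ftra[c] += fl.transmitted * f[c];
        frou[c] += fl.roulette * f[c];
      }
    }
    if ((i & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  double np = (double)n_photons;
  NumericVector abs_layer(nl);
  for (int l = 0; l < nl; ++l) abs_layer[l] = exc.absorbed[l] / np;
  List excitation = List::create(
    _["detected"] = exc.detected / np,
    _["absorbed_by_layer"] = abs_layer,
    _["escaped"] = exc.escaped / np,
    _["transmitted"] = exc.transmitted / np,
    _["roulette_net"] = exc.roulette / np);

  List out = List::create(
    _["excitation"] = excitation,
    _["n_photons"] = n_photons,
    _["seed"] = seed);

  if (n_depth_bins > 0) {
    NumericVector dh(n_depth_bins);
    for (int b = 0; b < n_depth_bins; ++b) dh[b] = depth_hist[b] / np;
    out["depth_profile"] = dh;
    out["depth_max_mm"] = depth_max_mm;
  }
  if (fluorescence) {
    NumericMatrix det(nl, 2);
    for (int l = 0; l < nl; ++l)
      for (int c = 0; c < 2; ++c) det(l, c) = fdet(l, c) / np;
    colnames(det) = CharacterVector::create("autofluorescence", "znpp");
    out["fluorescence"] = List::create(
      _["generated"] = NumericVector::create(_["autofluorescence"] = gen[0] / np,
                                             _["znpp"] = gen[1] / np),
      _["detected_by_layer"] = det,
      _["detected"] = NumericVector::create(_["autofluorescence"] = fdet_tot[0] / np,
                                            _["znpp"] = fdet_tot[1] / np),
      _["absorbed"] = NumericVector::create(_["autofluorescence"] = fabs[0] / np,
                                            _["znpp"] = fabs[1] / np),
      _["escaped"] = NumericVector::create(_["autofluorescence"] = fesc[0] / np,
                                           _["znpp"] = fesc[1] / np),
      _["transmitted"] = NumericVector::create(_["autofluorescence"] = ftra[0] / np,
                                               _["znpp"] = ftra[1] / np),
      _["roulette_net"] = NumericVector::create(_["autofluorescence"] = frou[0] / np,
                                                _["znpp"] = frou[1] / np));
  }
  return out;
}

// Oracle helper: isotropic point source at (0, 0, depth) in vacuum under
// the fibre; detected fraction has the closed form (1 - cos(theta*)) / 2
// with theta* = min(atan(r/depth), asin(NA/n_tissue)).
// [[Rcpp::export(name = ".mc_point_emission_cpp")]]
double mc_point_emission_cpp(double depth_mm, double r_fib_mm, double na,
                             double n_tissue, int n_photons, double seed) {
  double na_t = na / n_tissue;
  double det = 0;
  for (int i = 0; i < n_photons; ++i) {
    RNG rng((uint64_t)seed, (uint64_t)i);
    double cz = 2.0 * rng.unif() - 1.0;
    if (cz >= 0) continue;   // moving away from the surface
    double sz = std::sqrt(1.0 - cz * cz);
    double t = depth_mm / (-cz);
    double rho = sz * t;
    if (rho <= r_fib_mm && sz <= na_t) det += 1.0;
  }
  return det / (double)n_photons;
}
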