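// Weighted Monte Carlo photon transport in laterally infinite layered media.
//
// Conventions (mirrored exactly by the R reference loop used in the tests):
//   * One photon at a time; per-photon random-number consumption order is
//     launch-x, launch-y, polar u, azimuth u, then per propagation step:
//     optical path u, [scatter: HG u, azimuth u], [roulette u when below
//     threshold].
//   * Step lengths are sampled as a dimensionless optical path -ln(u) and
//     traversed across layer boundaries (matched internal refractive
//     indices; Fresnel only at the top tissue/ambient interface).
//   * Absorption weighting: each interaction deposits w * mua/mut.
//   * Top-surface escape uses deterministic weight splitting: the Fresnel
//     transmitted fraction exits (detected if inside the detector annulus),
//     the reflected fraction keeps propagating.
//   * Russian roulette below `w_threshold` with survival probability
//     `p_survive`; the signed weight created/retired by roulette is
//     accumulated so that detected + escaped + absorbed - roulette_net
//     equals the launched weight to floating-point accuracy.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

// splitmix64: seed expansion / substream derivation
static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sm);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1]; never exactly 0 so that -log(u) is finite
  inline double runif() {
    double u = (next() >> 11) * 0x1.0p-53;
    return (u <= 0.0) ? 0x1.0p-53 : u;
  }
};

struct Layer {
  double z0, z1, mua, mus, g;
  // derived per-layer constants (filled once before the photon loop)
  double mut, inv_mut, af;  // af = mua/mut (absorbed share per interaction)
};

static inline void sincos_(double a, double *s, double *c) {
#if defined(__GNUC__) && !defined(__APPLE__)
  ::sincos(a, s, c);
#else
  *s = std::sin(a);
  *c = std::cos(a);
#endif
}

// unpolarized Fresnel reflectance for incidence cosine ci, indices ni -> nt
static double fresnel_R(double ni, double nt, double ci) {
  if (ci > 1.0) ci = 1.0;
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double st = si * ni / nt;
  if (st >= 1.0) return 1.0;  // total internal reflection
  double ct = std::sqrt(std::max(0.0, 1.0 - st * st));
  if (si < 1e-12) {  // normal incidence
    double r = (ni - nt) / (ni + nt);
    return r * r;
  }
  double rs = (ni * ci - nt * ct) / (ni * ci + nt * ct);
  double rp = (ni * ct - nt * ci) / (ni * ct + nt * ci);
  return 0.5 * (rs * rs + rp * rp);
}

}  // namespace

// [[Rcpp::export(name = ".mc_engine")]]
List mc_engine(NumericMatrix layers,  // columns: z0 z1 mua mus g
               double n_tissue, double n_ambient,
               double src_side, double src_half_angle,
               double det_inner, double det_outer, int det_bottom,
               double n_photons, double seed,
               double w_threshold, double p_survive,
               double max_steps,
               NumericVector mua_perturbed) {
  // When `mua_perturbed` is non-empty it gives an alternative absorption
  // coefficient per layer; the same photon paths are reweighted exactly
  // (correlated/perturbation sampling: the scattering coefficients are
  // unchanged, so the path-measure ratio collapses to
  // exp(-sum_l dmua_l * pathlength_l)), yielding the perturbed detected
  // fraction from the very same random stream.
  const int nl = layers.nrow();
  std::vector<Layer> L(nl);
  for (int i = 0; i < nl; ++i) {
    Layer ly;
    ly.z0 = layers(i, 0); ly.z1 = layers(i, 1);
    ly.mua = layers(i, 2); ly.mus = layers(i, 3); ly.g = layers(i, 4);
    ly.mut = ly.mua + ly.mus;
    ly.inv_mut = ly.mut > 0.0 ? 1.0 / ly.mut : 0.0;
    ly.af = ly.mut > 0.0 ? ly.mua / ly.mut : 0.0;
    L[i] = ly;
  }
  const double z_bottom = L[nl - 1].z1;
  const long long N = (long long)n_photons;
  if (N < 1) stop("n_photons must be >= 1");
  const bool perturb = mua_perturbed.size() == nl;
  std::vector<double> dmua(nl, 0.0), plen(nl, 0.0);
  if (perturb)
    for (int i = 0; i < nl; ++i) dmua[i] = mua_perturbed[i] - L[i].mua;

  Xoshiro256pp rng((uint64_t)seed);

  const double sin_max = std::sin(std::min(src_half_angle, M_PI / 2.0));
  const double sin2_max = sin_max * sin_max;
  const bool matched = std::fabs(n_tissue - n_ambient) < 1e-12;

  double detected = 0.0, escaped = 0.0, absorbed = 0.0, bottom = 0.0,
         roulette_net = 0.0, detected_pert = 0.0, total_steps = 0.0;
  long long n_detected_photons = 0;

  for (long long ph = 0; ph < N; ++ph) {
    // launch position (uniform over square source) and Lambertian direction
    double u1 = rng.runif(), u2 = rng.runif();
    double x = (u1 - 0.5) * src_side, y = (u2 - 0.5) * src_side, z = 0.0;
    double u3 = rng.runif(), u4 = rng.runif();
    double si = std::sqrt(u3 * sin2_max);       // sin(theta_i) in ambient
    double ci = std::sqrt(1.0 - si * si);       // cos(theta_i)
    double phi = 2.0 * M_PI * u4;
    double w = 1.0;
    double ux, uy, uz;
    double sphi, cphi;
    sincos_(phi, &sphi, &cphi);
    if (matched) {
      ux = si * cphi;
      uy = si * sphi;
      uz = ci;
    } else {
      // refract into the tissue; specular/angular reflection escapes
      double R = fresnel_R(n_ambient, n_tissue, ci);
      escaped += R;
      w = 1.0 - R;
      double st = si * n_ambient / n_tissue;
      double ct = std::sqrt(std::max(0.0, 1.0 - st * st));
      ux = st * cphi;
      uy = st * sphi;
      uz = ct;
    }
    double inv_uz = uz != 0.0 ? 1.0 / uz : 0.0;

    int lay = 0;
    bool alive = true;
    double steps = 0.0;
    if (perturb) std::fill(plen.begin(), plen.end(), 0.0);
    while (alive) {
      if (++steps > max_steps) {  // safety cap; retire remaining weight
        absorbed += w;
        break;
      }
      double s = -std::log(rng.runif());  // optical path to next interaction
      // traverse layers until the optical path is exhausted
      while (s > 0.0) {
        const Layer &ly = L[lay];
        double db;  // geometric distance to the boundary ahead
        if (uz > 0.0)
          db = (ly.z1 - z) * inv_uz;
        else if (uz < 0.0)
          db = (ly.z0 - z) * inv_uz;  // uz < 0 and z0 <= z => db >= 0
        else
          db = R_PosInf;
        double ds = db * ly.mut;  // optical thickness to that boundary
        if (ds <= s) {
          // move to the boundary
          if (std::isfinite(db)) {
            x += ux * db;
            y += uy * db;
            if (perturb) plen[lay] += db;
          }
          s -= ds;
          if (uz < 0.0 && lay == 0 && ly.z0 <= 0.0) {
            // top surface
            z = 0.0;
            if (matched) {
              double r = std::sqrt(x * x + y * y);
              if (!det_bottom && r >= det_inner && r <= det_outer) {
                detected += w;
                ++n_detected_photons;
                if (perturb) {
                  double lr = 0.0;
                  for (int i = 0; i < nl; ++i) lr += dmua[i] * plen[i];
                  detected_pert += w * std::exp(-lr);
                }
              } else {
                escaped += w;
              }
              alive = false;
              break;
            }
            double R = fresnel_R(n_tissue, n_ambient, -uz);
            double T = 1.0 - R;
            if (T > 0.0) {
              double r = std::sqrt(x * x + y * y);
              if (!det_bottom && r >= det_inner && r <= det_outer) {
                detected += w * T;
                ++n_detected_photons;
                if (perturb) {
                  double lr = 0.0;
                  for (int i = 0; i < nl; ++i) lr += dmua[i] * plen[i];
                  detected_pert += w * T * std::exp(-lr);
                }
              } else {
                escaped += w * T;
              }
            }
            w *= R;
            uz = -uz;
            inv_uz = -inv_uz;
            if (w <= 0.0) { alive = false; break; }
          } else if (uz > 0.0 && lay == nl - 1 && ly.z1 >= z_bottom) {
            // bottom boundary: absorbing (or a bottom-surface detector)
            z = z_bottom;
            double r = std::sqrt(x * x + y * y);
            if (det_bottom && r >= det_inner && r <= det_outer) {
              detected += w;
              ++n_detected_photons;
              if (perturb) {
                double lr = 0.0;
                for (int i = 0; i < nl; ++i) lr += dmua[i] * plen[i];
                detected_pert += w * std::exp(-lr);
              }
            } else {
              bottom += w;
            }
            alive = false;
            break;
          } else {
            // internal boundary crossing (matched indices)
            if (uz > 0.0) {
              z = ly.z1;
              ++lay;
            } else {
              z = ly.z0;
              --lay;
            }
          }
        } else {
          // interaction inside the current layer
          double d = s * ly.inv_mut;
          x += ux * d;
          y += uy * d;
          z += uz * d;
          if (perturb) plen[lay] += d;
          s = 0.0;
          double dep = w * ly.af;
          absorbed += dep;
          w -= dep;
          if (w <= 0.0 || ly.mus <= 0.0) {
            // everything deposited (pure absorber): photon retired
            absorbed += w;
            w = 0.0;
            alive = false;
            break;
          }
          // Henyey-Greenstein scatter
          double g = ly.g;
          double u5 = rng.runif(), u6 = rng.runif();
          double ct;
          if (std::fabs(g) > 1e-12) {
            double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u5);
            ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
          } else {
            ct = 2.0 * u5 - 1.0;
          }
          if (ct > 1.0) ct = 1.0;
          if (ct < -1.0) ct = -1.0;
          double st = std::sqrt(1.0 - ct * ct);
          double psi = 2.0 * M_PI * u6;
          double cp, sp;
          sincos_(psi, &sp, &cp);
          if (std::fabs(uz) > 0.99999) {
            ux = st * cp;
            uy = st * sp;
            uz = (uz >= 0.0 ? ct : -ct);
          } else {
            double den = std::sqrt(1.0 - uz * uz);
            double inv_den = 1.0 / den;
            double nux = st * (ux * uz * cp - uy * sp) * inv_den + ux * ct;
            double nuy = st * (uy * uz * cp + ux * sp) * inv_den + uy * ct;
            double nuz = -den * st * cp + uz * ct;
            ux = nux;
            uy = nuy;
            uz = nuz;
          }
          inv_uz = uz != 0.0 ? 1.0 / uz : 0.0;
        }
      }
      if (!alive) break;
      // Russian roulette
      if (w < w_threshold) {
        double u7 = rng.runif();
        if (u7 < p_survive) {
          double w_new = w / p_survive;
          roulette_net += w_new - w;
          w = w_new;
        } else {
          roulette_net -= w;
          alive = false;
        }
      }
    }
    total_steps += steps;
  }

  double launched = (double)N;
  return List::create(
      _["detected"] = detected / launched,
      _["escaped"] = escaped / launched,
      _["absorbed_interior"] = absorbed / launched,
      _["absorbed_bottom"] = bottom / launched,
      _["roulette_net"] = roulette_net / launched,
      _["n_detected_photons"] = (double)n_detected_photons,
      _["detected_perturbed"] = perturb ? detected_pert / launched : NA_REAL,
      _["mean_steps"] = total_steps / launched);
}

// [[Rcpp::export(name = ".mc_rng_stream")]]
NumericVector mc_rng_stream(double seed, double n) {
  long long N = (long long)n;
  NumericVector out(N);
  Xoshiro256pp rng((uint64_t)seed);
  for (long long i = 0; i < N; ++i) out[i] = rng.runif();
  return out;
}

// [[Rcpp::export(name = ".mc_derive_seed")]]
double mc_derive_seed(double master, double k) {
  uint64_t state = (uint64_t)master;
  uint64_t out = 0;
  long long kk = (long long)k;
  for (long long i = 0; i <= kk; ++i) out = splitmix64(state);
  // keep derived seeds exactly representable as doubles
  return (double)(out & ((1ULL << 53) - 1ULL));
}
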