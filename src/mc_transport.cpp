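#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Layered-slab time-resolved photon transport without absorption
// (microscopic Lambert-Beer mode) or with direct absorption sampling.
//
// Geometry: the medium occupies z > 0; layer j spans
// [boundary[j-1], boundary[j]) with boundary[0] = 0 and the last layer
// semi-infinite. All layers share the interior refractive index, so the
// only refracting interface is the top surface (Fresnel, unpolarized).
// Photons start at the origin heading +z. Distances in cm, mus in 1/cm.
//
// Free paths are sampled as an optical depth consumed across layers
// (exponential memorylessness makes per-layer resampling exact).

// xoshiro256++ PRNG (Blackman & Vigna), seeded via splitmix64 from the
// user-supplied integer seed: fast, high-quality, and fully deterministic
// given (seed, parameters) independently of R's global RNG state.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
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
  // uniform in (0, 1]; never 0, so -log() is always finite
  inline double runif() {
    return (static_cast<double>(next() >> 11) + 1.0) * 0x1.0p-53;
  }
};

static inline double fresnel_R(double cos_i, double n_rel) {
  // n_rel = n_in / n_out; photon travelling from inside (n_in) to outside.
  if (n_rel == 1.0) return 0.0;
  double sin_i2 = 1.0 - cos_i * cos_i;
  double sin_t2 = n_rel * n_rel * sin_i2;
  if (sin_t2 >= 1.0) return 1.0;  // total internal reflection
  double cos_t = std::sqrt(1.0 - sin_t2);
  // amplitude coefficients with n1 = n_in, n2 = n_out, n1/n2 = n_rel
  double rs = (n_rel * cos_i - cos_t) / (n_rel * cos_i + cos_t);
  double rp = (cos_t * n_rel - cos_i) / (cos_t * n_rel + cos_i);
  // rp above uses n1 cos_t vs n2 cos_i divided through by n2
  return 0.5 * (rs * rs + rp * rp);
}

// [[Rcpp::export]]
List mc_transport_cpp(NumericVector thickness,   // per layer, last entry ignored (semi-infinite)
                      NumericVector mus,          // scattering coefficient per layer, 1/cm
                      double g,                   // Henyey-Greenstein anisotropy
                      double n_rel,               // n_in / n_out at the top surface
                      double rho,                 // nominal source-detector distance, cm
                      double ring_hw,             // ring half-width, cm
                      bool accept_all,            // detect every exiting photon
                      double path_max,            // abandon trajectories beyond this path length, cm
                      int n_target,               // detected photons wanted
                      double max_launch,          // launch budget
                      NumericVector mua,          // per-layer absorption for direct mode
                      bool direct_absorption,
                      int seed) {
  const int L = thickness.size();
  if (mus.size() != L) stop("mus and thickness must have equal length");
  std::vector<double> zlo(L), zhi(L);
  {
    double z = 0.0;
    for (int j = 0; j < L; ++j) {
      zlo[j] = z;
      z = (j == L - 1) ? R_PosInf : z + thickness[j];
      zhi[j] = z;
    }
  }

  NumericMatrix pathlen(n_target, L);
  NumericVector exit_path(n_target), exit_radius(n_target), max_depth(n_target);
  int detected = 0;
  double launched = 0.0;
  unsigned long tick = 0;

  Xoshiro rng(static_cast<uint64_t>(static_cast<int64_t>(seed)) + 0x5bd1e995ULL);
  const double tiny = 1e-12;
  std::vector<double> Lpath(L);

  while (detected < n_target && launched < max_launch) {
    launched += 1.0;
    if ((++tick & 0x3FFFF) == 0) Rcpp::checkUserInterrupt();
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    int layer = 0;
    double total = 0.0, zmax = 0.0;
    std::fill(Lpath.begin(), Lpath.end(), 0.0);
    bool alive = true, exited = false;
    double tau = -std::log(rng.runif());

    while (alive) {
      double mus_l = mus[layer];
      // in direct-absorption mode collisions occur at the total
      // interaction rate mut = mus + mua; otherwise transport is
      // absorption-free and mut = mus
      double mut_l = direct_absorption ? mus_l + mua[layer] : mus_l;
      double d_tau = (mut_l > 0.0) ? tau / mut_l : R_PosInf;
      double d_bnd;
      int next_layer = layer;
      bool to_surface = false;
      if (uz > tiny) {
        d_bnd = (zhi[layer] - z) / uz;
        next_layer = layer + 1;
      } else if (uz < -tiny) {
        d_bnd = (zlo[layer] - z) / uz;
        next_layer = layer - 1;
        to_surface = (layer == 0);
      } else {
        d_bnd = R_PosInf;
      }
      double d = std::min(d_tau, d_bnd);

      if (total + d > path_max) { alive = false; break; }

      x += ux * d; y += uy * d; z += uz * d;
      total += d;
      Lpath[layer] += d;
      if (z > zmax) zmax = z;
      tau -= d * mut_l;

      // feasibility pruning (exact, unbiased): a photon must still travel
      // at least the straight-line distance to the nearest detectable exit
      // point; if that exceeds the remaining path budget it can never be
      // detected within the time cap. Since that distance is bounded by
      // sqrt(r^2 + z^2), the sqrt is only taken once the bound can bite.
      {
        double rem = path_max - total;
        double r2 = x * x + y * y;
        if (rem * rem < r2 + z * z) {
          double dr = 0.0;
          if (!accept_all) {
            double rr = std::sqrt(r2);
            if (rr < rho - ring_hw) dr = (rho - ring_hw) - rr;
            else if (rr > rho + ring_hw) dr = rr - (rho + ring_hw);
          }
          if (dr * dr + z * z > rem * rem) { alive = false; break; }
        }
      }

      if (d_tau <= d_bnd) {
        // collision: in direct mode it is an absorption event with
        // probability mua/mut, otherwise a scattering event
        if (direct_absorption && mua[layer] > 0.0) {
          if (rng.runif() < mua[layer] / mut_l) { alive = false; break; }
        }
        if (g == 0.0) {
          // isotropic: the new direction is uniform on the sphere and does
          // not depend on the old one (Marsaglia sphere picking, trig-free)
          for (;;) {
            double v1 = 2.0 * rng.runif() - 1.0;
            double v2 = 2.0 * rng.runif() - 1.0;
            double ss = v1 * v1 + v2 * v2;
            if (ss < 1.0) {
              double f2 = 2.0 * std::sqrt(1.0 - ss);
              ux = v1 * f2; uy = v2 * f2; uz = 1.0 - 2.0 * ss;
              break;
            }
          }
        } else {
          // Henyey-Greenstein deflection about the current direction
          double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.runif());
          double ct = (1.0 + g * g - f * f) / (2.0 * g);
          if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
          double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
          double cp, sp;
          for (;;) {
            double v1 = 2.0 * rng.runif() - 1.0;
            double v2 = 2.0 * rng.runif() - 1.0;
            double ss = v1 * v1 + v2 * v2;
            if (ss > 0.0 && ss < 1.0) {
              cp = (v1 * v1 - v2 * v2) / ss;
              sp = 2.0 * v1 * v2 / ss;
              break;
            }
          }
          if (std::fabs(uz) > 0.99999) {
            ux = st * cp; uy = st * sp; uz = ct * (uz > 0 ? 1.0 : -1.0);
          } else {
            double denom = std::sqrt(1.0 - uz * uz);
            double nux = st * (ux * uz * cp - uy * sp) / denom + ux * ct;
            double nuy = st * (uy * uz * cp + ux * sp) / denom + uy * ct;
            double nuz = -st * cp * denom + uz * ct;
            double norm = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
            ux = nux / norm; uy = nuy / norm; uz = nuz / norm;
          }
        }
        tau = -std::log(rng.runif());
      } else {
        // boundary hit
        if (to_surface) {
          z = 0.0;
          double cos_i = std::fabs(uz);
          if (rng.runif() < fresnel_R(cos_i, n_rel)) {
            uz = -uz;  // internal reflection, keep remaining optical depth
          } else {
            exited = true; alive = false;
          }
        } else {
          layer = next_layer;
          // snap to the exact boundary to avoid drift
          if (uz > 0) z = zlo[layer]; else z = zhi[layer];
        }
      }
    }

    if (exited) {
      double r = std::sqrt(x * x + y * y);
      if (accept_all || std::fabs(r - rho) <= ring_hw) {
        for (int j = 0; j < L; ++j) pathlen(detected, j) = Lpath[j];
        exit_path[detected] = total;
        exit_radius[detected] = r;
        max_depth[detected] = zmax;
        ++detected;
      }
    }
  }

  bool budget_exhausted = (detected < n_target);
  if (budget_exhausted) {
    pathlen = pathlen(Range(0, std::max(detected - 1, 0)), _);
    exit_path = head(exit_path, detected);
    exit_radius = head(exit_radius, detected);
    max_depth = head(max_depth, detected);
  }
  return List::create(_["pathlen"] = pathlen,
                      _["exit_path"] = exit_path,
                      _["exit_radius"] = exit_radius,
                      _["max_depth"] = max_depth,
                      _["n_launched"] = launched,
                      _["budget_exhausted"] = budget_exhausted);
}
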