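#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// xoshiro256++ generator, seeded through splitmix64.  A self-contained
// counter-free generator keeps the photon walk reproducible bit-for-bit for
// a given seed, independent of R's RNG state.
namespace {

struct Xoshiro256 {
  uint64_t s[4];

  explicit Xoshiro256(uint64_t seed) {
    // splitmix64 expansion of the 64-bit seed into the 256-bit state
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
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

  // uniform double in (0, 1]; never returns 0 so log() is always finite
  inline double runif_pos() {
    return ((next() >> 11) + 1.0) * 0x1.0p-53;
  }

  // uniform double in [0, 1)
  inline double runif() {
    return (next() >> 11) * 0x1.0p-53;
  }

  // cosine/sine of a uniform azimuth, by rejection from the unit disc
  // (avoids trig calls in the inner loop)
  inline void azimuth(double &c, double &s) {
    double a, b, r2;
    do {
      a = 2.0 * runif() - 1.0;
      b = 2.0 * runif() - 1.0;
      r2 = a * a + b * b;
    } while (r2 > 1.0 || r2 == 0.0);
    c = (a * a - b * b) / r2;
    s = 2.0 * a * b / r2;
  }
};

// unpolarized Fresnel reflection coefficient for a photon inside the medium
// (index n_in) hitting the planar interface with the exterior (index n_out)
// at incidence cosine ci > 0
inline double fresnel_R(double ci, double n_in, double n_out) {
  if (ci > 1.0) ci = 1.0;
  const double si2 = 1.0 - ci * ci;
  const double ratio = n_in / n_out;
  const double st2 = ratio * ratio * si2;  // sin^2 of transmitted angle
  if (st2 >= 1.0) return 1.0;              // total internal reflection
  const double ct = std::sqrt(1.0 - st2);
  if (si2 < 1e-12) {                       // normal incidence limit
    const double r = (n_in - n_out) / (n_in + n_out);
    return r * r;
  }
  const double rs = (n_in * ci - n_out * ct) / (n_in * ci + n_out * ct);
  const double rp = (n_in * ct - n_out * ci) / (n_in * ct + n_out * ci);
  return 0.5 * (rs * rs + rp * rp);
}

}  // namespace

// Photon random walk in a semi-infinite homogeneous medium (z >= 0), pencil
// beam normally incident at the origin.  Scattering coefficient mu_s with
// Henyey-Greenstein anisotropy g; absorption applied continuously along the
// path as exp(-mu_a * segment) (mu_a = 0 gives the scattering-only "white"
// run re-weighted later).  The index-mismatched boundary applies unpolarized
// Fresnel reflection; transmitted photons exit carrying their full current
// weight (probabilistic splitting at the interface).
//
// Returns exit weight binned by (exit radius, total path length), the total
// launched weight, the weight terminated without exiting through the top
// surface, and optional direct spatial-frequency projections
// sum_i w_i cos(2*pi*fx*x_i) over exit events.
//
// [[Rcpp::export(name = ".mc_walk")]]
List mc_walk(double n_photons, double mu_s, double mu_a, double g,
             double n_in, double n_out,
             double radial_bin_width, int n_radial,
             double path_bin_width, int n_path,
             double weight_min, double survival_factor,
             NumericVector proj_fx, double seed) {
  if (mu_s <= 0) stop("mu_s must be positive");
  if (g < 0 || g >= 1) stop("anisotropy g must lie in [0, 1)");
  if (n_in < 1 || n_out < 1) stop("refractive indices must be >= 1");

  const double max_radius = radial_bin_width * n_radial;
  const double max_path = path_bin_width * n_path;
  const R_xlen_t nr = n_radial, nl = n_path;

  NumericMatrix weights(nr, nl);
  const int nfx = proj_fx.size();
  std::vector<double> proj(nfx, 0.0);
  double proj_total = 0.0;  // sum of exit weights (all radii), for projections
  double lost = 0.0;

  Xoshiro256 rng(static_cast<uint64_t>(seed));
  const R_xlen_t N = static_cast<R_xlen_t>(n_photons);
  const bool iso = (g < 1e-12);
  const double two_pi = 2.0 * M_PI;

  for (R_xlen_t ip = 0; ip < N; ++ip) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0, path = 0.0;
    bool alive = true;

    while (alive) {
      double s = -std::log(rng.runif_pos()) / mu_s;

      // advance, handling any boundary encounters within the step
      while (s > 0.0) {
        double d = s;
        bool hit = false;
        if (uz < 0.0) {
          const double db = -z / uz;
          if (db <= s) { d = db; hit = true; }
        }
        x += ux * d; y += uy * d; z += uz * d;
        path += d;
        if (mu_a > 0.0) {  // continuous absorption, booked to the ledger
          const double wa = w * std::exp(-mu_a * d);
          lost += w - wa;
          w = wa;
        }
        s -= d;

        // a photon needs at least path length z to regain the surface, so
        // one whose depth exceeds its remaining path budget can never exit
        // within max_path: terminating it early is exact, not approximate
        if (path >= max_path || z > max_path - path) {
          lost += w;
          alive = false;
          break;
        }

        if (hit) {
          z = 0.0;
          const double R = fresnel_R(-uz, n_in, n_out);
          if (rng.runif() < R) {
            uz = -uz;  // internal reflection, continue remaining sub-step
          } else {
            // photon exits through the top surface
            const double r = std::sqrt(x * x + y * y);
            if (r < max_radius) {
              const R_xlen_t ir = static_cast<R_xlen_t>(r / radial_bin_width);
              const R_xlen_t il = static_cast<R_xlen_t>(path / path_bin_width);
              weights(ir, il) += w;
            } else {
              lost += w;  // beyond the tallied field: booked as lost
            }
            proj_total += w;
            for (int k = 0; k < nfx; ++k)
              proj[k] += w * std::cos(two_pi * proj_fx[k] * x);
            alive = false;
            break;
          }
        }
      }
      if (!alive) break;

      // scatter: Henyey-Greenstein deflection, uniform azimuth
      double ct;
      if (iso) {
        ct = 2.0 * rng.runif() - 1.0;
      } else {
        const double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.runif());
        ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
        if (ct > 1.0) ct = 1.0;
        if (ct < -1.0) ct = -1.0;
      }
      const double st = std::sqrt(1.0 - ct * ct);
      double cp, sp;
      rng.azimuth(cp, sp);

      if (std::fabs(uz) > 0.99999) {
        ux = st * cp;
        uy = st * sp;
        uz = ct * (uz >= 0.0 ? 1.0 : -1.0);
      } else {
        const double den = std::sqrt(1.0 - uz * uz);
        const double nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        const double nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        const double nuz = -st * cp * den + uz * ct;
        ux = nux; uy = nuy; uz = nuz;
      }

      // Russian roulette on low-weight photons (only engages when mu_a > 0);
      // the weight created on survival is debited from the lost ledger so
      // launched = exited + lost holds exactly, not just in expectation
      if (w < weight_min) {
        if (rng.runif() * survival_factor < 1.0) {
          lost -= (survival_factor - 1.0) * w;
          w *= survival_factor;
        } else {
          lost += w;
          alive = false;
        }
      }
    }
  }

  return List::create(
      _["weights"] = weights,
      _["launched_weight"] = static_cast<double>(N),
      _["absorbed_or_lost_weight"] = lost,
      _["projection"] = NumericVector(proj.begin(), proj.end()),
      _["projection_total"] = proj_total);
}
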