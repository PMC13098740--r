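// Layered-slab Monte Carlo photon transport.
//
// Geometry: z positive downward, surface at z = 0, pencil beam entering at
// the origin along +z. Layers are horizontal slabs; the last layer is
// semi-infinite. The detector is an annulus centred on the source at radius
// `sds` with half-width `half_width`.
//
// Transport is "white" by default: steps are sampled from mu_s only and
// absorption is applied afterwards via Beer-Lambert weights on the recorded
// per-layer pathlengths. A baked-in mode (mua_baked > 0) attenuates the
// weight continuously along the path instead; both are unbiased estimators
// of the same reflectance and the two routes are compared in the tests.
//
// Per detected photon the engine records per-layer pathlength L_j and
// per-layer dimensionless momentum transfer Y_j = sum over scattering
// events in layer j of (1 - cos(theta)).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

// splitmix64, used to seed xoshiro256++
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
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1]; never returns 0 so -log(u) is finite
  inline double runif_open() {
    return ((next() >> 11) + 1.0) * 0x1.0p-53;
  }
  // uniform in [0, 1)
  inline double runif() {
    return (next() >> 11) * 0x1.0p-53;
  }
};

// unpolarized Fresnel reflectance for a ray hitting a horizontal interface
// with |cos(incidence)| = ci, going from index n1 into n2
static inline double fresnel_R(double n1, double n2, double ci) {
  if (n1 == n2) return 0.0;
  double si2 = 1.0 - ci * ci;
  double st2 = (n1 / n2) * (n1 / n2) * si2;
  if (st2 >= 1.0) return 1.0;  // total internal reflection
  double ct = std::sqrt(1.0 - st2);
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".fresnel_reflectance_cpp")]]
double fresnel_reflectance_cpp(double n1, double n2, double cos_incident) {
  return fresnel_R(n1, n2, cos_incident);
}

// mua_ref implements survival-based reference absorption: each photon draws
// an exponential absorption path ~ Exp(mua_ref) at launch and terminates
// there. Detected weights are compensated on the R side by
// exp(+mua_ref * total_path), which keeps any downstream Beer-Lambert
// reweighting with per-layer mua >= mua_ref unbiased while cutting the cost
// of deep zero-absorption excursions.
// [[Rcpp::export(name = ".mc_layered_cpp")]]
List mc_layered_cpp(NumericVector thickness,
                    NumericVector mus,
                    NumericVector g,
                    NumericVector n_layer,
                    NumericVector mua_baked,
                    double n_ambient,
                    double sds,
                    double half_width,
                    double n_photons,
                    double max_total_path,
                    double roulette_threshold,
                    double roulette_survival,
                    double mua_ref,
                    double seed,
                    IntegerVector record_idx,
                    int n_record) {
  // "zones" are the transport strata (possibly finer than the reported
  // layers, e.g. the deep similarity zone of the bottom layer); record_idx
  // maps each zone to the reported layer its pathlength/momentum transfer
  // accumulates into (1-based).
  const int nl = thickness.size();
  if (mus.size() != nl || g.size() != nl || n_layer.size() != nl ||
      mua_baked.size() != nl || record_idx.size() != nl)
    stop("zone property vectors must have equal length");
  if (nl < 1) stop("need at least one zone");
  std::vector<int> rec(nl);
  for (int l = 0; l < nl; ++l) {
    rec[l] = record_idx[l] - 1;
    if (rec[l] < 0 || rec[l] >= n_record) stop("record_idx out of range");
  }

  // layer interfaces: z_bot[l] is the lower boundary of layer l
  std::vector<double> z_bot(nl), z_top(nl);
  double zcum = 0.0;
  for (int l = 0; l < nl; ++l) {
    z_top[l] = zcum;
    zcum += thickness[l];
    z_bot[l] = (l == nl - 1) ? std::numeric_limits<double>::infinity() : zcum;
  }

  const long long N = (long long)(n_photons + 0.5);
  Xoshiro256pp rng((uint64_t)seed);

  std::vector<double> det_L, det_Y, det_w, det_r;
  long long n_detected = 0;

  double specular_w = 0.0, escaped_w = 0.0, killed_w = 0.0,
         absorbed_w = 0.0, detected_w = 0.0, roulette_gain = 0.0,
         absorbed_ref_w = 0.0;

  std::vector<double> L(n_record), Y(n_record);
  const double r_lo = sds - half_width, r_hi = sds + half_width;
  const bool baked = [&] {
    for (int l = 0; l < nl; ++l) if (mua_baked[l] > 0.0) return true;
    return false;
  }();

  const double Rsp = fresnel_R(n_ambient, n_layer[0], 1.0);

  for (long long ip = 0; ip < N; ++ip) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    int layer = 0;
    double w = 1.0 - Rsp;
    specular_w += Rsp;
    double path = 0.0;
    std::fill(L.begin(), L.end(), 0.0);
    std::fill(Y.begin(), Y.end(), 0.0);
    double tau_left = -std::log(rng.runif_open());
    double abs_path = (mua_ref > 0.0)
        ? -std::log(rng.runif_open()) / mua_ref
        : std::numeric_limits<double>::infinity();
    bool alive = true;

    while (alive) {
      const double mus_l = mus[layer];
      double s_int = (mus_l > 0.0) ? tau_left / mus_l
                                   : std::numeric_limits<double>::infinity();
      double s_b;
      if (uz > 0.0)       s_b = (z_bot[layer] - z) / uz;
      else if (uz < 0.0)  s_b = (z_top[layer] - z) / uz;  // both negative
      else                s_b = std::numeric_limits<double>::infinity();
      if (s_b < 0.0) s_b = 0.0;  // numerical guard

      bool to_boundary = s_b <= s_int;
      double s = to_boundary ? s_b : s_int;

      const double stop_path = (abs_path < max_total_path) ? abs_path
                                                           : max_total_path;
      if (path + s >= stop_path) {   // reference absorption or path cap
        s = stop_path - path;
        x += s * ux; y += s * uy; z += s * uz;
        L[rec[layer]] += s; path += s;
        if (baked) {
          double w2 = w * std::exp(-mua_baked[layer] * s);
          absorbed_w += w - w2; w = w2;
        }
        if (abs_path < max_total_path) absorbed_ref_w += w;
        else                           killed_w += w;
        break;
      }

      x += s * ux; y += s * uy; z += s * uz;
      L[rec[layer]] += s; path += s;
      if (baked) {
        double w2 = w * std::exp(-mua_baked[layer] * s);
        absorbed_w += w - w2; w = w2;
      }

      if (!to_boundary) {
        // scattering event: Henyey-Greenstein deflection
        const double gl = g[layer];
        double cost;
        if (std::fabs(gl) < 1e-12) {
          cost = 2.0 * rng.runif() - 1.0;
        } else {
          double tmp = (1.0 - gl * gl) / (1.0 - gl + 2.0 * gl * rng.runif());
          cost = (1.0 + gl * gl - tmp * tmp) / (2.0 * gl);
          if (cost > 1.0) cost = 1.0; else if (cost < -1.0) cost = -1.0;
        }
        Y[rec[layer]] += 1.0 - cost;
        const double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
        // uniform azimuth via Marsaglia rejection (no sincos call)
        double u1, u2, ss;
        do {
          u1 = 2.0 * rng.runif() - 1.0;
          u2 = 2.0 * rng.runif() - 1.0;
          ss = u1 * u1 + u2 * u2;
        } while (ss > 1.0 || ss == 0.0);
        const double cosp = (u1 * u1 - u2 * u2) / ss;
        const double sinp = 2.0 * u1 * u2 / ss;
        if (std::fabs(uz) > 0.99999) {
          ux = sint * cosp;
          uy = sint * sinp;
          uz = (uz >= 0.0) ? cost : -cost;
        } else {
          const double den = std::sqrt(1.0 - uz * uz);
          const double nx = (sint * (ux * uz * cosp - uy * sinp)) / den + ux * cost;
          const double ny = (sint * (uy * uz * cosp + ux * sinp)) / den + uy * cost;
          const double nz = -den * sint * cosp + uz * cost;
          ux = nx; uy = ny; uz = nz;
        }
        tau_left = -std::log(rng.runif_open());

        if (baked && w < roulette_threshold) {     // Russian roulette
          if (rng.runif() < roulette_survival) {
            double gain = w * (1.0 / roulette_survival - 1.0);
            roulette_gain += gain;
            w /= roulette_survival;
          } else {
            killed_w += w;
            break;
          }
        }
      } else {
        // interface handling
        tau_left -= s * mus_l;
        if (tau_left < 0.0) tau_left = 0.0;
        const bool upward = uz < 0.0;
        const double ci = std::fabs(uz);
        double n1 = n_layer[layer];
        double n2;
        int next_layer;
        if (upward) {
          next_layer = layer - 1;
          n2 = (layer == 0) ? n_ambient : n_layer[next_layer];
          z = z_top[layer];
        } else {
          next_layer = layer + 1;  // bottom layer never reaches here
          n2 = n_layer[next_layer];
          z = z_bot[layer];
        }
        const double R = fresnel_R(n1, n2, ci);
        bool reflect = (R >= 1.0) || (R > 0.0 && rng.runif() < R);
        if (reflect) {
          uz = -uz;
        } else {
          if (n1 != n2) {  // refract
            const double ratio = n1 / n2;
            ux *= ratio; uy *= ratio;
            const double st2 = ux * ux + uy * uy;
            const double ct = std::sqrt(std::max(0.0, 1.0 - st2));
            uz = upward ? -ct : ct;
          }
          if (upward && layer == 0) {
            // photon leaves through the top surface
            const double r = std::sqrt(x * x + y * y);
            if (r >= r_lo && r <= r_hi) {
              for (int l = 0; l < n_record; ++l) det_L.push_back(L[l]);
              for (int l = 0; l < n_record; ++l) det_Y.push_back(Y[l]);
              det_w.push_back(w);
              det_r.push_back(r);
              detected_w += w;
              ++n_detected;
            } else {
              escaped_w += w;
            }
            alive = false;
          } else {
            layer = next_layer;
          }
        }
      }
    }
  }

  NumericMatrix Lmat(n_record, (int)n_detected), Ymat(n_record, (int)n_detected);
  std::copy(det_L.begin(), det_L.end(), Lmat.begin());
  std::copy(det_Y.begin(), det_Y.end(), Ymat.begin());

  return List::create(
    _["L"] = Lmat,                 // layers x detected (transposed in R)
    _["Y"] = Ymat,
    _["exit_weight"] = NumericVector(det_w.begin(), det_w.end()),
    _["detector_distance"] = NumericVector(det_r.begin(), det_r.end()),
    _["n_launched"] = (double)N,
    _["n_detected"] = (double)n_detected,
    _["totals"] = List::create(
      _["specular"] = specular_w,
      _["detected"] = detected_w,
      _["escaped"] = escaped_w,
      _["killed"] = killed_w,
      _["absorbed"] = absorbed_w,
      _["absorbed_ref"] = absorbed_ref_w,
      _["roulette_gain"] = roulette_gain));
}
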