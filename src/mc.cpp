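#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---- counter-based RNG: splitmix64 seeding + xoshiro256++ per-packet streams

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(seed);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  // uniform in (0, 1): never exactly 0 (log() safe), never 1
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// ---- physics helpers

static inline double fresnel_R(double n1, double n2, double cosi) {
  double sini = std::sqrt(std::max(0.0, 1.0 - cosi * cosi));
  double sint = n1 / n2 * sini;
  if (sint >= 1.0) return 1.0;
  double cost = std::sqrt(1.0 - sint * sint);
  double rs = (n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost);
  double rp = (n1 * cost - n2 * cosi) / (n1 * cost + n2 * cosi);
  return 0.5 * (rs * rs + rp * rp);
}

static inline void hg_scatter(double g, double u1, double u2,
                              double &wx, double &wy, double &wz) {
  double ct;
  if (std::fabs(g) < 1e-6) {
    ct = 1.0 - 2.0 * u1;
  } else {
    double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * u1);
    ct = (1.0 + g * g - t * t) / (2.0 * g);
  }
  ct = std::min(1.0, std::max(-1.0, ct));
  double st = std::sqrt(1.0 - ct * ct);
  double phi = 2.0 * M_PI * u2, cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(wz) > 0.99999) {
    wx = st * cp; wy = st * sp; wz = ct * (wz >= 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - wz * wz);
    double nx = st * (wx * wz * cp - wy * sp) / den + wx * ct;
    double ny = st * (wy * wz * cp + wx * sp) / den + wy * ct;
    double nz = -den * st * cp + wz * ct;
    wx = nx; wy = ny; wz = nz;
  }
  double norm = std::sqrt(wx * wx + wy * wy + wz * wz);
  wx /= norm; wy /= norm; wz /= norm;
}

// terminal event codes
enum { EV_DETECTED = 0, EV_ESCAPED = 1, EV_TRANSMITTED = 2,
       EV_ROULETTE = 3, EV_TRUNCATED = 4 };

// [[Rcpp::export(name = ".mc_run_cpp")]]
List mc_run_cpp(NumericVector mu_a, NumericVector mu_s, NumericVector g,
                NumericVector n_layer, NumericVector thickness,
                double n_ambient,
                double src_x, double theta_in_deg,
                double det_x, double det_half_x, double det_half_y,
                double na_half_angle_deg,
                int n_photons, double seed,
                double roulette_threshold, double roulette_survival,
                int max_interactions, bool return_events) {
  const int L = mu_a.size();
  std::vector<double> zb(L + 1); // layer i occupies [zb[i], zb[i+1])
  zb[0] = 0.0;
  for (int i = 0; i < L; ++i)
    zb[i + 1] = zb[i] + (std::isfinite(thickness[i]) ? thickness[i] : 1e30);

  const double th = theta_in_deg * M_PI / 180.0;
  const double cos_na = std::cos(na_half_angle_deg * M_PI / 180.0);

  double detected = 0, escaped = 0, transmitted = 0, absorbed = 0,
         truncated = 0;
  double sum_d = 0, sum_d2 = 0, sum_r = 0, sum_r2 = 0;
  long long detected_n = 0;
  IntegerVector events(return_events ? n_photons : 0);

  for (int ip = 0; ip < n_photons; ++ip) {
    uint64_t pseed = (uint64_t)seed * 0x9E3779B97F4A7C15ULL + (uint64_t)ip;
    Xoshiro rng(pseed);

    double x = src_x, y = 0.0, z = 0.0, W = 1.0;
    double wx = std::sin(th), wy = 0.0, wz = std::cos(th);
    int layer = -1;               // ambient, entering through the top surface
    int ev = EV_TRUNCATED;
    double d_i = 0.0, r_i = 0.0;  // per-packet detected / top-exit weight
    int steps = 0;
    bool alive = true;

    // entry interaction air -> first layer
    {
      double R = fresnel_R(n_ambient, n_layer[0], std::fabs(wz));
      if (rng.unif() < R) { // specular reflection off the surface, exits up
        double exit_cos = std::fabs(wz);
        bool in_ap = std::fabs(x - det_x) <= det_half_x &&
                     std::fabs(y) <= det_half_y && exit_cos >= cos_na;
        if (in_ap) { detected += W; d_i = W; detected_n++; ev = EV_DETECTED; }
        else { escaped += W; ev = EV_ESCAPED; }
        r_i = W;
        alive = false;
      } else {
        double scale = n_ambient / n_layer[0];
        wx *= scale; wy *= scale;
        wz = std::sqrt(std::max(0.0, 1.0 - wx * wx - wy * wy));
        layer = 0;
      }
    }

    while (alive) {
      if (++steps > max_interactions) { truncated += W; ev = EV_TRUNCATED; break; }
      double ms = mu_s[layer], ma = mu_a[layer];
      // distance to layer boundary along current direction
      double db;
      int dir; // +1 moving down, -1 moving up
      if (wz > 1e-12) { db = (zb[layer + 1] - z) / wz; dir = 1; }
      else if (wz < -1e-12) { db = (zb[layer] - z) / wz; dir = -1; }
      else { db = 1e30; dir = 0; }
      double l = (ms > 0.0) ? -std::log(rng.unif()) / ms : 1e30;

      if (l < db) {
        // free-path move + scattering event
        x += wx * l; y += wy * l; z += wz * l;
        double f = std::exp(-ma * l);
        absorbed += W * (1.0 - f); W *= f;
        hg_scatter(g[layer], rng.unif(), rng.unif(), wx, wy, wz);
      } else {
        if (dir == 0) { truncated += W; ev = EV_TRUNCATED; break; }
        // move to boundary
        x += wx * db; y += wy * db; z = (dir > 0) ? zb[layer + 1] : zb[layer];
        double f = std::exp(-ma * db);
        absorbed += W * (1.0 - f); W *= f;
        int nb = layer + dir;
        double n1 = n_layer[layer];
        double n2 = (nb < 0) ? n_ambient : (nb >= L ? n_layer[L - 1] : n_layer[nb]);
        double cosi = std::fabs(wz);
        double R = fresnel_R(n1, n2, cosi);
        if (rng.unif() < R) {
          wz = -wz; // specular reflection, stay in layer
        } else {
          double scale = n1 / n2;
          wx *= scale; wy *= scale;
          double s2 = wx * wx + wy * wy;
          double nwz = std::sqrt(std::max(0.0, 1.0 - s2));
          wz = (wz >= 0) ? nwz : -nwz;
          if (nb < 0) { // exits through the top surface into ambient
            double exit_cos = std::fabs(wz);
            bool in_ap = std::fabs(x - det_x) <= det_half_x &&
                         std::fabs(y) <= det_half_y && exit_cos >= cos_na;
            if (in_ap) { detected += W; d_i = W; detected_n++; ev = EV_DETECTED; }
            else { escaped += W; ev = EV_ESCAPED; }
            r_i = W;
            break;
          }
          if (nb >= L) { transmitted += W; ev = EV_TRANSMITTED; break; }
          layer = nb;
        }
      }
      // unbiased Russian roulette on low weights
      if (W < roulette_threshold) {
        if (rng.unif() < roulette_survival) {
          double Wnew = W / roulette_survival;
          absorbed += W - Wnew; // negative credit keeps the ledger exact
          W = Wnew;
        } else {
          absorbed += W; ev = EV_ROULETTE; break;
        }
      }
    }
    sum_d += d_i; sum_d2 += d_i * d_i;
    sum_r += r_i; sum_r2 += r_i * r_i;
    if (return_events) events[ip] = ev;
  }

  double N = (double)n_photons;
  double mean_d = sum_d / N, mean_r = sum_r / N;
  double se_d = (N > 1) ? std::sqrt(std::max(0.0, (sum_d2 / N - mean_d * mean_d) / (N - 1))) : NA_REAL;
  double se_r = (N > 1) ? std::sqrt(std::max(0.0, (sum_r2 / N - mean_r * mean_r) / (N - 1))) : NA_REAL;

  List out = List::create(
    _["detected_weight"] = detected, _["detected_count"] = (double)detected_n,
    _["escaped_weight"] = escaped, _["transmitted_weight"] = transmitted,
    _["absorbed_weight"] = absorbed, _["truncated_weight"] = truncated,
    _["launched_weight"] = N,
    _["reflectance"] = mean_d, _["reflectance_se"] = se_d,
    _["total_reflectance"] = mean_r, _["total_reflectance_se"] = se_r);
  if (return_events) out["events"] = events;
  return out;
}
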