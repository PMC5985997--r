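#ifndef FCSFIT_RNG_H
#define FCSFIT_RNG_H

#include <cstdint>
#include <cmath>

// Self-contained RNG so that seed -> trace is bit-stable across platforms
// and R versions (the package's determinism contract).

struct Xoshiro256pp {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  explicit Xoshiro256pp(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
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

  // uniform in [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  // uniform in (0, 1]
  inline double unif_pos() { return ((next() >> 11) + 1) * 0x1.0p-53; }
};

// Marsaglia-Tsang ziggurat for standard normals (128 strips).
struct Ziggurat {
  uint32_t kn[128];
  double wn[128], fn[128];
  Xoshiro256pp *rng;

  explicit Ziggurat(Xoshiro256pp *r) : rng(r) {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }

  double nfix(int32_t hz, int iz) {
    const double r = 3.442619855899, rinv = 1.0 / r;
    double x, y;
    for (;;) {
      x = hz * wn[iz];
      if (iz == 0) {  // tail
        do {
          x = -std::log(rng->unif_pos()) * rinv;
          y = -std::log(rng->unif_pos());
        } while (y + y < x * x);
        return (hz > 0) ? r + x : -r - x;
      }
      if (fn[iz] + rng->unif() * (fn[iz - 1] - fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
      hz = (int32_t)rng->next();
      iz = hz & 127;
      if ((uint32_t)std::abs(hz) < kn[iz]) return hz * wn[iz];
    }
  }

  inline double rnorm() {
    int32_t hz = (int32_t)rng->next();
    int iz = hz & 127;
    return ((uint32_t)std::abs(hz) < kn[iz]) ? hz * wn[iz] : nfix(hz, iz);
  }
};

// Poisson sampler: inversion for small means, Hormann's PTRS otherwise.
inline double rpois_one(Xoshiro256pp &rng, double mu) {
  if (mu <= 0.0) return 0.0;
  if (mu < 10.0) {
    double L = std::exp(-mu), p = 1.0;
    double k = 0.0;
    do {
      ++k;
      p *= rng.unif_pos();
    } while (p > L);
    return k - 1.0;
  }
  const double b = 0.931 + 2.53 * std::sqrt(mu);
  const double a = -0.059 + 0.02483 * b;
  const double invalpha = 1.1239 + 1.1328 / (b - 3.4);
  const double vr = 0.9277 - 3.6224 / (b - 2.0);
  for (;;) {
    double u = rng.unif() - 0.5;
    double v = rng.unif_pos();
    double us = 0.5 - std::fabs(u);
    double k = std::floor((2.0 * a / us + b) * u + mu + 0.43);
    if (us >= 0.07 && v <= vr) return k;
    if (k < 0.0 || (us < 0.013 && v > us)) continue;
    if (std::log(v * invalpha / (a / (us * us) + b)) <=
        k * std::log(mu) - mu - std::lgamma(k + 1.0))
      return k;
  }
}

#endif
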