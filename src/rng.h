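#ifndef PHAGEPACK_RNG_H
#define PHAGEPACK_RNG_H

#include <cstdint>
#include <cmath>

// Self-contained counter-free PRNG (xoshiro256++) with splitmix64 seeding.
// Streams are derived from (master seed, stream id) so every replicate and
// protocol stage gets an independent, reproducible sequence.

namespace pp {

inline std::uint64_t splitmix64(std::uint64_t &s) {
  std::uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

class RNG {
 public:
  RNG() { seed(1, 0); }
  RNG(std::uint64_t master, std::uint64_t stream) { seed(master, stream); }

  void seed(std::uint64_t master, std::uint64_t stream) {
    std::uint64_t s = master * 0x9E3779B97F4A7C15ULL + stream * 0xD1B54A32D192ED03ULL + 1ULL;
    for (int i = 0; i < 4; ++i) st_[i] = splitmix64(s);
    have_norm_ = false;
  }

  std::uint64_t next() {
    const std::uint64_t result = rotl(st_[0] + st_[3], 23) + st_[0];
    const std::uint64_t t = st_[1] << 17;
    st_[2] ^= st_[0];
    st_[3] ^= st_[1];
    st_[1] ^= st_[2];
    st_[0] ^= st_[3];
    st_[2] ^= t;
    st_[3] = rotl(st_[3], 45);
    return result;
  }

  // uniform in [0, 1)
  double unif() { return (next() >> 11) * 0x1.0p-53; }

  // uniform in [lo, hi)
  double unif(double lo, double hi) { return lo + (hi - lo) * unif(); }

  // standard normal (Box-Muller, cached second deviate)
  double norm() {
    if (have_norm_) { have_norm_ = false; return cached_; }
    double u1, u2;
    do { u1 = unif(); } while (u1 <= 0.0);
    u2 = unif();
    const double r = std::sqrt(-2.0 * std::log(u1));
    const double a = 6.283185307179586476925286766559 * u2;
    cached_ = r * std::sin(a);
    have_norm_ = true;
    return r * std::cos(a);
  }

  // Gamma(shape >= 1, scale 1), Marsaglia-Tsang squeeze method
  double gamma(double shape) {
    const double d = shape - 1.0 / 3.0;
    const double c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
      double x = norm();
      double v = 1.0 + c * x;
      if (v <= 0.0) continue;
      v = v * v * v;
      const double u = unif();
      if (u < 1.0 - 0.0331 * x * x * x * x) return d * v;
      if (u > 0.0 && std::log(u) < 0.5 * x * x + d * (1.0 - v + std::log(v))) return d * v;
    }
  }

  // random unit vector, uniform on the sphere
  void unit_vector(double out[3]) {
    const double z = 2.0 * unif() - 1.0;
    const double phi = 6.283185307179586476925286766559 * unif();
    const double s = std::sqrt(1.0 > z * z ? 1.0 - z * z : 0.0);
    out[0] = s * std::cos(phi);
    out[1] = s * std::sin(phi);
    out[2] = z;
  }

 private:
  static std::uint64_t rotl(std::uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  std::uint64_t st_[4];
  bool have_norm_;
  double cached_;
};

}  // namespace pp

#endif
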