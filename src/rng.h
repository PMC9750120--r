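#pragma once
#include <cstdint>
#include <cstring>
#include <cmath>
#include <Rcpp.h>

// xoshiro256++ with splitmix64 seeding: platform-independent streams so that
// (params, seed) -> identical trajectories on any machine, independent of R's RNG.
struct Xoshiro {
  uint64_t s[4];

  static uint64_t splitmix(uint64_t& x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
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
  double unif() { return (next() >> 11) * 0x1.0p-53; }

  // exponential waiting time, rate per unit time
  double expo(double rate) { return -std::log1p(-unif()) / rate; }

  // uniform integer in {0, ..., n-1}
  int unif_int(int n) {
    return (int)(((__uint128_t)next() * (uint64_t)n) >> 64);
  }

  Rcpp::RawVector save() const {
    Rcpp::RawVector r(32);
    std::memcpy(RAW(r), s, 32);
    return r;
  }

  static Xoshiro load(const Rcpp::RawVector& r) {
    Xoshiro g(0);
    std::memcpy(g.s, RAW(r), 32);
    return g;
  }
};
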