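#ifndef RBPFOREST_RNG_H
#define RBPFOREST_RNG_H

#include <cstdint>

// Self-contained counter-free PRNG (splitmix64 seeding + xorshift64*).
// Used instead of R's RNG so that fitted forests are bit-identical for a
// given integer seed regardless of the caller's RNG state or R version.
struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) {
    // splitmix64 scrambles small consecutive seeds into distant states
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s = z ^ (z >> 31);
    if (s == 0) s = 0x9E3779B97F4A7C15ULL;
  }
  uint64_t next() {
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // uniform integer in [0, n); n must be >= 1
  int unif_int(int n) {
    // rejection sampling to avoid modulo bias
    uint64_t bound = UINT64_MAX - (UINT64_MAX % (uint64_t)n);
    uint64_t v;
    do { v = next(); } while (v >= bound);
    return (int)(v % (uint64_t)n);
  }
};

#endif
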