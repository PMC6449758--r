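#ifndef BC_RNG_H
#define BC_RNG_H

#include <cstdint>
#include <Rcpp.h>

// Counter-free xoroshiro128+ streams.  Each cell agent owns one stream,
// seeded from (master seed, agent id) via splitmix64, so trajectories are
// reproducible independently of the order in which agents are updated.

static inline uint64_t bc_splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct BCRng {
  uint64_t s0, s1;

  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }

  uint64_t next_u64() {
    uint64_t r = s0 + s1;
    uint64_t t = s1 ^ s0;
    s0 = rotl(s0, 55) ^ t ^ (t << 14);
    s1 = rotl(t, 36);
    return r;
  }

  // uniform in (0, 1]: strictly positive so log() is always finite
  double unif_pos() {
    return ((next_u64() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }

  // uniform in [0, 1)
  double unif() {
    return (next_u64() >> 11) * (1.0 / 9007199254740992.0);
  }

  double exp_rand(double rate) {
    return -std::log(unif_pos()) / rate;
  }

  void seed_from(uint64_t master, uint64_t id) {
    uint64_t x = master * 0x9E3779B97F4A7C15ULL + id * 0xD1B54A32D192ED03ULL + 1ULL;
    s0 = bc_splitmix64(x);
    s1 = bc_splitmix64(x);
    if (s0 == 0 && s1 == 0) s1 = 0x1ULL;
  }
};

// pack/unpack a stream into an R integer(4) (two uint64 as 4 x uint32)
static inline BCRng bc_load(const int *p) {
  BCRng r;
  r.s0 = ((uint64_t)(uint32_t)p[0]) | (((uint64_t)(uint32_t)p[1]) << 32);
  r.s1 = ((uint64_t)(uint32_t)p[2]) | (((uint64_t)(uint32_t)p[3]) << 32);
  return r;
}

static inline void bc_store(const BCRng &r, int *p) {
  p[0] = (int)(uint32_t)(r.s0 & 0xFFFFFFFFULL);
  p[1] = (int)(uint32_t)(r.s0 >> 32);
  p[2] = (int)(uint32_t)(r.s1 & 0xFFFFFFFFULL);
  p[3] = (int)(uint32_t)(r.s1 >> 32);
}

#endif
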