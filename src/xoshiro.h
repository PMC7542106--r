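#ifndef BLOCKCPM_XOSHIRO_H
#define BLOCKCPM_XOSHIRO_H

#include <cstdint>
#include <cstring>

// xoshiro256++ with splitmix64 seeding; one independent stream per block.
// State is held R-side as a 32-byte raw vector so runs are reproducible and
// restartable, mirroring a per-rank generator in a distributed code.

namespace bcrng {

struct Stream {
  uint64_t s[4];
};

inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

inline uint64_t splitmix64(uint64_t& x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

inline void seed_stream(Stream& g, uint64_t seed, uint64_t stream_id) {
  uint64_t x = seed ^ (0xD1B54A32D192ED03ULL * (stream_id + 1));
  for (int i = 0; i < 4; ++i) g.s[i] = splitmix64(x);
}

inline uint64_t next(Stream& g) {
  const uint64_t result = rotl(g.s[0] + g.s[3], 23) + g.s[0];
  const uint64_t t = g.s[1] << 17;
  g.s[2] ^= g.s[0];
  g.s[3] ^= g.s[1];
  g.s[1] ^= g.s[2];
  g.s[0] ^= g.s[3];
  g.s[2] ^= t;
  g.s[3] = rotl(g.s[3], 45);
  return result;
}

inline double runif01(Stream& g) { return (next(g) >> 11) * (1.0 / 9007199254740992.0); }

// uniform on {0, ..., n-1}; n is small (< 2^31)
inline int runif_int(Stream& g, int n) {
  int k = (int)(runif01(g) * n);
  return k >= n ? n - 1 : k;
}

inline void load_stream(Stream& g, const unsigned char* raw) { std::memcpy(g.s, raw, 32); }
inline void save_stream(const Stream& g, unsigned char* raw) { std::memcpy(raw, g.s, 32); }

}  // namespace bcrng

#endif
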