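#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <cstdio>

// MurmurHash3 x64 128-bit variant; we keep the first 64-bit word (h1).
// Hashes are returned as fixed-width lowercase hex so that R, which has no
// native 64-bit integer, can order and compare them exactly: lexicographic
// order on 16-digit hex equals unsigned numeric order.

static inline uint64_t rotl64(uint64_t x, int8_t r) {
  return (x << r) | (x >> (64 - r));
}

static inline uint64_t fmix64(uint64_t k) {
  k ^= k >> 33;
  k *= 0xff51afd7ed558ccdULL;
  k ^= k >> 33;
  k *= 0xc4ceb9fe1a85ec53ULL;
  k ^= k >> 33;
  return k;
}

static uint64_t murmur3_x64_128_h1(const char* key, int len, uint32_t seed) {
  const uint8_t* data = (const uint8_t*)key;
  const int nblocks = len / 16;

  uint64_t h1 = seed;
  uint64_t h2 = seed;

  const uint64_t c1 = 0x87c37b91114253d5ULL;
  const uint64_t c2 = 0x4cf5ad432745937fULL;

  for (int i = 0; i < nblocks; i++) {
    uint64_t k1, k2;
    std::memcpy(&k1, data + i * 16, 8);
    std::memcpy(&k2, data + i * 16 + 8, 8);

    k1 *= c1; k1 = rotl64(k1, 31); k1 *= c2; h1 ^= k1;
    h1 = rotl64(h1, 27); h1 += h2; h1 = h1 * 5 + 0x52dce729;
    k2 *= c2; k2 = rotl64(k2, 33); k2 *= c1; h2 ^= k2;
    h2 = rotl64(h2, 31); h2 += h1; h2 = h2 * 5 + 0x38495ab5;
  }

  const uint8_t* tail = data + nblocks * 16;
  uint64_t k1 = 0, k2 = 0;

  switch (len & 15) {
  case 15: k2 ^= ((uint64_t)tail[14]) << 48; /* fallthrough */
  case 14: k2 ^= ((uint64_t)tail[13]) << 40; /* fallthrough */
  case 13: k2 ^= ((uint64_t)tail[12]) << 32; /* fallthrough */
  case 12: k2 ^= ((uint64_t)tail[11]) << 24; /* fallthrough */
  case 11: k2 ^= ((uint64_t)tail[10]) << 16; /* fallthrough */
  case 10: k2 ^= ((uint64_t)tail[9])  << 8;  /* fallthrough */
  case  9: k2 ^= ((uint64_t)tail[8]);
           k2 *= c2; k2 = rotl64(k2, 33); k2 *= c1; h2 ^= k2;
           /* fallthrough */
  case  8: k1 ^= ((uint64_t)tail[7]) << 56;  /* fallthrough */
  case  7: k1 ^= ((uint64_t)tail[6]) << 48;  /* fallthrough */
  case  6: k1 ^= ((uint64_t)tail[5]) << 40;  /* fallthrough */
  case  5: k1 ^= ((uint64_t)tail[4]) << 32;  /* fallthrough */
  case  4: k1 ^= ((uint64_t)tail[3]) << 24;  /* fallthrough */
  case  3: k1 ^= ((uint64_t)tail[2]) << 16;  /* fallthrough */
  case  2: k1 ^= ((uint64_t)tail[1]) << 8;   /* fallthrough */
  case  1: k1 ^= ((uint64_t)tail[0]);
           k1 *= c1; k1 = rotl64(k1, 31); k1 *= c2; h1 ^= k1;
  }

  h1 ^= len; h2 ^= len;
  h1 += h2; h2 += h1;
  h1 = fmix64(h1); h2 = fmix64(h2);
  h1 += h2; /* h2 += h1 not needed for first word */

  return h1;
}

// [[Rcpp::export(name = ".mm3_hash64_hex")]]
Rcpp::CharacterVector mm3_hash64_hex(Rcpp::CharacterVector x, int seed) {
  int n = x.size();
  Rcpp::CharacterVector out(n);
  char buf[17];
  for (int i = 0; i < n; i++) {
    if (Rcpp::CharacterVector::is_na(x[i])) {
      out[i] = NA_STRING;
      continue;
    }
    const char* s = x[i];
    uint64_t h = murmur3_x64_128_h1(s, (int)std::strlen(s), (uint32_t)seed);
    std::snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
    out[i] = buf;
  }
  return out;
}
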