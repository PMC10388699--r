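#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <algorithm>
using namespace Rcpp;

// splitmix64: fast, well-mixed 64-bit permutation; used as a counter-based
// PRF so every random decision is a pure function of (seed, stream, counter)
// and never depends on worker scheduling or the caller's RNG state.
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t mix3(uint64_t seed, uint64_t stream, uint64_t counter) {
  uint64_t h = splitmix64(seed);
  h = splitmix64(h ^ stream);
  h = splitmix64(h ^ counter);
  return h;
}

// Uniform doubles in [0, 1) from the top 53 bits of the PRF output.
// [[Rcpp::export(name = ".prf_u01")]]
NumericVector prf_u01_cpp(double seed, double stream, NumericVector counter) {
  R_xlen_t n = counter.size();
  NumericVector out(n);
  uint64_t s = (uint64_t)(int64_t)seed;
  uint64_t st = (uint64_t)(int64_t)stream;
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t h = mix3(s, st, (uint64_t)(int64_t)counter[i]);
    out[i] = (double)(h >> 11) * (1.0 / 9007199254740992.0); /* 2^53 */
  }
  return out;
}

// FNV-1a 64-bit over the key bytes, reduced modulo m. Stable across runs and
// platforms (no per-process randomization); used only to ROUTE keys to
// partitions — grouping itself always compares full key values.
// [[Rcpp::export(name = ".hash_mod")]]
IntegerVector hash_mod_cpp(CharacterVector keys, int m) {
  R_xlen_t n = keys.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t h = 0xCBF29CE484222325ULL;
    const char *p = CHAR(STRING_ELT(keys, i));
    while (*p) {
      h ^= (uint64_t)(unsigned char)(*p++);
      h *= 0x100000001B3ULL;
    }
    out[i] = (int)(h % (uint64_t)m);
  }
  return out;
}

// Reverse each string byte-wise (sequences are ASCII).
// [[Rcpp::export(name = ".rev_strings")]]
CharacterVector rev_strings_cpp(CharacterVector x) {
  R_xlen_t n = x.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (x[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    std::string s(CHAR(STRING_ELT(x, i)));
    std::reverse(s.begin(), s.end());
    out[i] = s;
  }
  return out;
}
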