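#include <Rcpp.h>
#include <cstdint>
#include <string>
using namespace Rcpp;

// Seeded 64-bit hashing over stable string keys. All sketch randomness in the
// package flows through these functions, keyed by (seed, stream), so results
// are identical across platforms and independent of R's RNG state.

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t fnv1a64(const char *s) {
  uint64_t h = 1469598103934665603ULL;
  for (; *s; ++s) {
    h ^= (unsigned char)(*s);
    h *= 1099511628211ULL;
  }
  return h;
}

static inline uint64_t key_hash(const char *s, uint64_t seed, uint64_t stream) {
  // mix the content hash with a per-(seed, stream) constant
  uint64_t salt = splitmix64(seed ^ (stream * 0xA24BAED4963EE407ULL) ^ 0x6C62272E07BB0142ULL);
  return splitmix64(fnv1a64(s) ^ salt);
}

static inline int count_leading_zeros(uint64_t w) {
  if (w == 0) return 64;
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_clzll(w);
#else
  int n = 0;
  for (uint64_t mask = 1ULL << 63; mask && !(w & mask); mask >>= 1) ++n;
  return n;
#endif
}

//' @name minhash_hash_keys
//' @noRd
// [[Rcpp::export(rng = false)]]
NumericMatrix minhash_hash_keys(CharacterVector keys, int num_perm, double seed) {
  // One column per key, one row per hash permutation. Values are the top 53
  // bits of the 64-bit hash so that they are exactly representable as doubles
  // (min-merge algebra over them stays bit-exact in R).
  const int n = keys.size();
  NumericMatrix out(num_perm, n);
  const uint64_t s = (uint64_t)(int64_t)seed;
  for (int j = 0; j < n; ++j) {
    const char *k = CHAR(STRING_ELT(keys, j));
    for (int i = 0; i < num_perm; ++i) {
      uint64_t h = key_hash(k, s, (uint64_t)(i + 1));
      out(i, j) = (double)(h >> 11);
    }
  }
  return out;
}

//' @name hll_hash_keys
//' @noRd
// [[Rcpp::export(rng = false)]]
List hll_hash_keys(CharacterVector keys, int precision, double seed) {
  // For each key: register index (1-based, from the top `precision` bits) and
  // the rank = 1 + number of leading zeros in the remaining 64 - p bits.
  const int n = keys.size();
  const uint64_t s = (uint64_t)(int64_t)seed;
  IntegerVector idx(n), rank(n);
  for (int j = 0; j < n; ++j) {
    uint64_t h = key_hash(CHAR(STRING_ELT(keys, j)), s, 0ULL);
    idx[j] = (int)(h >> (64 - precision)) + 1;
    uint64_t rest = h << precision; // remaining bits, left-aligned
    int r = count_leading_zeros(rest) + 1;
    int rmax = 64 - precision + 1;
    if (r > rmax) r = rmax;
    rank[j] = r;
  }
  return List::create(_["index"] = idx, _["rank"] = rank);
}

//' @name ngram_bucket_sign
//' @noRd
// [[Rcpp::export(rng = false)]]
List ngram_bucket_sign(CharacterVector grams, int dim, double seed) {
  // Feature-hashing for the offline embedder: bucket in 1..dim and a +/-1 sign
  // per n-gram, both derived from independent hash streams.
  const int n = grams.size();
  const uint64_t s = (uint64_t)(int64_t)seed;
  IntegerVector bucket(n);
  NumericVector sign(n);
  for (int j = 0; j < n; ++j) {
    const char *g = CHAR(STRING_ELT(grams, j));
    uint64_t hb = key_hash(g, s, 0x5EEDULL);
    uint64_t hs = key_hash(g, s, 0x51C4ULL);
    bucket[j] = (int)(hb % (uint64_t)dim) + 1;
    sign[j] = (hs & 1ULL) ? 1.0 : -1.0;
  }
  return List::create(_["bucket"] = bucket, _["sign"] = sign);
}
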