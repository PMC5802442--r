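#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Counter-based uniform generator (SplitMix64 finalizer over a keyed counter).
// Every stochastic quantity in the simulator is an inverse-CDF transform of
// u = hash(master_seed, person_id, stream, counter), so a person's draws are
// reproducible in isolation and identical across scenarios by construction.

static inline uint64_t splitmix64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double key_uniform(uint64_t seed, uint64_t id,
                                 uint64_t stream, uint64_t counter) {
  uint64_t z = splitmix64(seed);
  z = splitmix64(z ^ (id * 0xD6E8FEB86659FD93ULL));
  z = splitmix64(z ^ (stream * 0xA3EC647659359ACDULL));
  z = splitmix64(z ^ (counter * 0xC2B2AE3D27D4EB4FULL));
  // 53-bit mantissa => u in [0, 1)
  return (double)(z >> 11) * (1.0 / 9007199254740992.0);
}

//' Keyed uniform draws for a named random substream
//'
//' @param seed master seed (non-negative integer-valued scalar)
//' @param person_id integer vector of person identifiers
//' @param stream integer substream code
//' @param counter integer vector (length 1 or length of person_id) indexing
//'   repeated draws within a substream (e.g., screening year)
//' @return numeric vector of uniforms in [0, 1), one per person
//' @keywords internal
// [[Rcpp::export]]
NumericVector substream_uniform(double seed, IntegerVector person_id,
                                int stream, IntegerVector counter) {
  R_xlen_t n = person_id.size();
  R_xlen_t nc = counter.size();
  if (nc != 1 && nc != n) stop("counter must have length 1 or length(person_id)");
  if (seed < 0) stop("seed must be non-negative");
  NumericVector out(n);
  uint64_t s = (uint64_t)seed;
  uint64_t st = (uint64_t)(uint32_t)stream;
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t id = (uint64_t)(uint32_t)person_id[i];
    uint64_t ct = (uint64_t)(uint32_t)(nc == 1 ? counter[0] : counter[i]);
    out[i] = key_uniform(s, id, st, ct);
  }
  return out;
}
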