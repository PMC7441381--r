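#include <Rcpp.h>
using namespace Rcpp;

// Backward dynamic-programming sampler for independent Bernoulli(p_i)
// conditioned on sum == m.  T[i][j] = P(sum of y_i..y_{n-1} == j), filled by
// the Poisson-binomial recursion; a draw then walks i = 0..n-1 assigning
// y_i = 1 with probability p_i * T[i+1][j-1] / T[i][j].
// Probabilities along any feasible path stay far from the double underflow
// threshold, so no log-scale arithmetic is needed.
// [[Rcpp::export(name = ".cb_dp_sample")]]
IntegerMatrix cb_dp_sample(NumericVector p, int m, int ndraws) {
  int n = p.size();
  if (m < 0 || m > n) stop("case total out of range");
  size_t W = (size_t)m + 1;
  std::vector<double> T((size_t)(n + 1) * W, 0.0);
  T[(size_t)n * W] = 1.0;
  for (int i = n - 1; i >= 0; --i) {
    double pi = p[i];
    size_t ri = (size_t)i * W, rn = (size_t)(i + 1) * W;
    int jmax = std::min(m, n - i);
    T[ri] = (1.0 - pi) * T[rn];
    for (int j = 1; j <= jmax; ++j)
      T[ri + j] = pi * T[rn + j - 1] + (1.0 - pi) * T[rn + j];
  }
  if (T[m] <= 0.0) stop("conditioning event has probability zero");
  IntegerMatrix out(ndraws, n);
  for (int d = 0; d < ndraws; ++d) {
    int j = m;
    for (int i = 0; i < n; ++i) {
      double denom = T[(size_t)i * W + j];
      double p1 = (j > 0) ? p[i] * T[(size_t)(i + 1) * W + j - 1] / denom : 0.0;
      if (unif_rand() < p1) { out(d, i) = 1; --j; } else { out(d, i) = 0; }
    }
  }
  return out;
}

// Fast local PRNG (xoshiro256++) for the rejection inner loop, seeded
// deterministically from R's RNG stream so results stay reproducible under
// set.seed() while avoiding the per-call overhead of unif_rand().
namespace {
inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97f4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}
struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(seed);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double runif() {  // uniform on [0, 1) with 53-bit resolution
    return (next() >> 11) * 0x1.0p-53;
  }
};
}  // namespace

// Rejection sampler: draw independent Bernoulli(p_i) and accept when the sum
// equals m.  Exact for the conditional law; the caller is expected to pass
// exponentially tilted p so that E[sum] == m (tilting multiplies every odds
// by the same constant and therefore leaves the conditional law unchanged,
// while making acceptance O(1/sd(sum)) instead of exponentially small).
// [[Rcpp::export(name = ".cb_reject_sample")]]
List cb_reject_sample(NumericVector p, int m, int ndraws, int max_tries) {
  int n = p.size();
  if (m < 0 || m > n) stop("case total out of range");
  // seed the fast generator from R's stream (keeps set.seed() determinism)
  uint64_t seed = (uint64_t)(unif_rand() * 4294967296.0) << 32;
  seed |= (uint64_t)(unif_rand() * 4294967296.0);
  Xoshiro256pp rng(seed);
  IntegerMatrix out(ndraws, n);
  std::vector<int> y(n);
  double tries_total = 0.0;
  for (int d = 0; d < ndraws; ++d) {
    bool ok = false;
    for (int t = 0; t < max_tries && !ok; ++t) {
      tries_total += 1.0;
      int s = 0;
      bool over = false;
      for (int i = 0; i < n; ++i) {
        int v = (rng.runif() < p[i]) ? 1 : 0;
        y[i] = v;
        s += v;
        if (s > m) { over = true; break; }
      }
      if (!over && s == m) {
        for (int i = 0; i < n; ++i) out(d, i) = y[i];
        ok = true;
      }
    }
    if (!ok) stop("rejection sampler exceeded max_tries; use method = \"dp\"");
  }
  return List::create(_["y"] = out, _["tries"] = tries_total);
}
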