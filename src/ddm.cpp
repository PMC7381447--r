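#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Counter-based RNG: every simulation attempt runs on its own splitmix64
// substream, keyed by (seed, trial, attempt). Two evaluations with the
// same key replay identical Gaussian increments, so objective values at
// nearby candidate parameters are tightly coupled (proper common random
// numbers) and stochastic-objective minima can be located precisely.
// Seeds are drawn from R's RNG by the R-level wrappers, so set.seed()
// still determines everything.
struct SubRng {
  uint64_t s;
  double spare;
  bool has;
  explicit SubRng(uint64_t seed) : s(seed), spare(0.0), has(false) {}
  inline uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  // Marsaglia polar method
  inline double norm() {
    if (has) {
      has = false;
      return spare;
    }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f;
    has = true;
    return u * f;
  }
};

static inline uint64_t attempt_key(uint64_t seed, uint64_t trial,
                                   uint64_t attempt) {
  // distinct odd multipliers keep substreams disjoint in practice
  return seed ^ (trial * 0xD1342543DE82EF95ULL) ^
         (attempt * 0xAF251AF3B0F025B5ULL);
}

// One accumulation attempt. The activation starts at 0 and each sample
// adds drift plus Gaussian noise; crossing +threshold (>=) is a correct
// response, -threshold (<=) an incorrect one. Returns +t for a correct
// crossing at sample t, -t for an incorrect crossing, 0 on timeout.
static inline int walk_once(SubRng &rng, double drift, double noise,
                            double threshold, int timeout) {
  double a = 0.0;
  for (int t = 1; t <= timeout; ++t) {
    a += drift + noise * rng.norm();
    if (a >= threshold) return t;
    if (a <= -threshold) return -t;
  }
  return 0;
}

// Simulate one response per element of `drifts`. A timed-out attempt is
// discarded and restarted from 0; after max_attempts timeouts the trial
// is flagged as failed (failed_index is 1-based; rt/correct NA from
// there on).
// [[Rcpp::export]]
List cpp_ddm_sim(NumericVector drifts, double noise, double threshold,
                 int timeout, int max_attempts, double seed) {
  uint64_t s = (uint64_t)seed;
  int n = drifts.size();
  IntegerVector rt(n, NA_INTEGER);
  LogicalVector correct(n, NA_LOGICAL);
  IntegerVector attempts(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    int res = 0, att = 0;
    while (att < max_attempts) {
      ++att;
      SubRng rng(attempt_key(s, i + 1, att));
      res = walk_once(rng, drifts[i], noise, threshold, timeout);
      if (res != 0) break;
    }
    attempts[i] = att;
    if (res == 0) {
      return List::create(_["rt"] = rt, _["correct"] = correct,
                          _["attempts"] = attempts, _["failed"] = true,
                          _["failed_index"] = i + 1);
    }
    rt[i] = res > 0 ? res : -res;
    correct[i] = res > 0;
  }
  return List::create(_["rt"] = rt, _["correct"] = correct,
                      _["attempts"] = attempts, _["failed"] = false,
                      _["failed_index"] = NA_INTEGER);
}

// Rejection-sample one response of the required correctness per element
// of `drifts`, holding each element's drift fixed across attempts (for
// mixture schedules the per-trial template draw happens upstream and is
// part of the trial's identity). Timed-out and wrong-category attempts
// both count against max_attempts.
// [[Rcpp::export]]
List cpp_ddm_sim_conditional(NumericVector drifts, bool required_correct,
                             double noise, double threshold, int timeout,
                             int max_attempts, double seed) {
  uint64_t s = (uint64_t)seed;
  int n = drifts.size();
  IntegerVector rt(n, NA_INTEGER);
  IntegerVector attempts(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    int att = 0, res = 0;
    bool ok = false;
    while (att < max_attempts) {
      ++att;
      SubRng rng(attempt_key(s, i + 1, att));
      res = walk_once(rng, drifts[i], noise, threshold, timeout);
      if ((res > 0 && required_correct) || (res < 0 && !required_correct)) {
        ok = true;
        break;
      }
    }
    attempts[i] = att;
    if (!ok) {
      return List::create(_["rt"] = rt, _["attempts"] = attempts,
                          _["failed"] = true, _["failed_index"] = i + 1);
    }
    rt[i] = res > 0 ? res : -res;
  }
  return List::create(_["rt"] = rt, _["attempts"] = attempts,
                      _["failed"] = false, _["failed_index"] = NA_INTEGER);
}

// Pool-filling sampler for cells that share one drift: simulate
// unconditionally and drop each outcome into the correct/incorrect pile
// until both hold their target counts (overflow discarded). Because
// trials are i.i.d., the first n outcomes of a category are i.i.d. draws
// from the category-conditional RT distribution — identical in law to
// per-response rejection, at roughly half the cost. Failure keeps the
// per-response semantics: max_attempts consecutive attempts without
// filling a still-needed pile exhaust the budget.
// [[Rcpp::export]]
List cpp_ddm_sim_pool(double drift, int n_correct, int n_incorrect,
                      double noise, double threshold, int timeout,
                      int max_attempts, double seed) {
  uint64_t s = (uint64_t)seed;
  IntegerVector cor(n_correct), inc(n_incorrect);
  int got_cor = 0, got_inc = 0, misses = 0;
  uint64_t j = 0;
  while (got_cor < n_correct || got_inc < n_incorrect) {
    if (misses >= max_attempts) {
      return List::create(
          _["correct_rt"] = cor, _["incorrect_rt"] = inc,
          _["failed"] = true,
          _["failed_category"] = got_cor < n_correct ? "correct"
                                                     : "incorrect");
    }
    ++j;
    SubRng rng(attempt_key(s, 0, j));
    int res = walk_once(rng, drift, noise, threshold, timeout);
    if (res > 0 && got_cor < n_correct) {
      cor[got_cor++] = res;
      misses = 0;
    } else if (res < 0 && got_inc < n_incorrect) {
      inc[got_inc++] = -res;
      misses = 0;
    } else {
      ++misses;
    }
  }
  return List::create(_["correct_rt"] = cor, _["incorrect_rt"] = inc,
                      _["failed"] = false, _["failed_category"] = R_NilValue);
}
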