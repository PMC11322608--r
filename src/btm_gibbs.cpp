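#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for the biterm topic model.
//
// Each biterm (unordered word pair drawn from one short document) carries a
// single topic assignment z. The collapsed conditional for reassigning a
// biterm b = (w1, w2) given all other assignments is
//
//   P(z = t | rest) ∝ (n_t + alpha) * (n_{w1|t} + beta) * (n_{w2|t} + beta)
//                     / ((n_{.|t} + V*beta) * (n_{.|t} + 1 + V*beta))
//
// where n_t counts biterms in topic t, n_{w|t} word slots of w in topic t,
// and n_{.|t} = 2 * n_t total word slots in topic t. Point estimates from
// the final counts:
//
//   phi_{t,w}   = (n_{w|t} + beta) / (n_{.|t} + V*beta)
//   theta_t     = (n_t + alpha) / (N_B + k*alpha)
//
// Sampling uses an internal xorshift128+ generator whose state is seeded
// from R's RNG, so a set.seed() in the caller makes the fit bit-identical
// while keeping the hot loop free of RNG dispatch overhead.

namespace {
struct Xorshift128p {
  uint64_t s0, s1;
  inline uint64_t next() {
    uint64_t x = s0;
    const uint64_t y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  // uniform double in [0, 1)
  inline double runif() {
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
};
}

// [[Rcpp::export]]
List btm_gibbs(const IntegerMatrix& biterms, int V, int k,
               double alpha, double beta, int n_iter) {
  const int N = biterms.nrow();
  if (N == 0) stop("corpus too sparse: no biterms");
  if (V < 1 || k < 1) stop("V and k must be >= 1");

  std::vector<int> z(N), bw1(N), bw2(N);
  for (int b = 0; b < N; ++b) {
    bw1[b] = biterms(b, 0) - 1;
    bw2[b] = biterms(b, 1) - 1;
    if (bw1[b] < 0 || bw1[b] >= V || bw2[b] < 0 || bw2[b] >= V)
      stop("word id out of range");
  }
  std::vector<double> n_t(k, 0.0);
  std::vector<double> n_wt((size_t)V * k, 0.0); // word-major: n_wt[w*k + t]

  Xorshift128p rng;
  {
    RNGScope scope;  // derive the internal state from R's seeded RNG
    rng.s0 = (uint64_t)(unif_rand() * 4294967296.0) << 32 |
             (uint64_t)(unif_rand() * 4294967296.0);
    rng.s1 = (uint64_t)(unif_rand() * 4294967296.0) << 32 |
             (uint64_t)(unif_rand() * 4294967296.0);
    if (rng.s0 == 0 && rng.s1 == 0) rng.s1 = 88172645463325252ULL;
    for (int warm = 0; warm < 8; ++warm) rng.next();
  }

  // random initialisation
  for (int b = 0; b < N; ++b) {
    int t = (int)(rng.runif() * k);
    if (t == k) t = k - 1;
    z[b] = t;
    n_t[t] += 1.0;
    n_wt[(size_t)bw1[b] * k + t] += 1.0;
    n_wt[(size_t)bw2[b] * k + t] += 1.0;
  }

  const double Vbeta = V * beta;
  // fused per-topic factor s[t] = (n_t + alpha) / denominator(t); the
  // denominator depends only on the integer biterm count of the topic, so
  // its reciprocal is tabulated once and the hot loop is division-free
  std::vector<double> tab(N + 1);
  for (int c = 0; c <= N; ++c) {
    const double ndot = 2.0 * c;
    tab[c] = 1.0 / ((ndot + Vbeta) * (ndot + 1.0 + Vbeta));
  }
  std::vector<double> s(k), p(k);
  auto refresh = [&](int t) {
    s[t] = (n_t[t] + alpha) * tab[(int)n_t[t]];
  };
  for (int t = 0; t < k; ++t) refresh(t);
  for (int it = 0; it < n_iter; ++it) {
    for (int b = 0; b < N; ++b) {
      const int w1 = bw1[b], w2 = bw2[b];
      const int old = z[b];
      n_t[old] -= 1.0;
      n_wt[(size_t)w1 * k + old] -= 1.0;
      n_wt[(size_t)w2 * k + old] -= 1.0;
      refresh(old);
      const double* r1 = &n_wt[(size_t)w1 * k];
      const double* r2 = &n_wt[(size_t)w2 * k];
      double tot = 0.0;
      for (int t = 0; t < k; ++t) {
        const double pt = s[t] * (r1[t] + beta) * (r2[t] + beta);
        p[t] = pt;
        tot += pt;
      }
      const double u = rng.runif() * tot;
      int t_new = 0;
      double acc = p[0];
      while (u > acc && t_new < k - 1) acc += p[++t_new];
      z[b] = t_new;
      n_t[t_new] += 1.0;
      n_wt[(size_t)w1 * k + t_new] += 1.0;
      n_wt[(size_t)w2 * k + t_new] += 1.0;
      refresh(t_new);
    }
  }

  NumericMatrix phi(k, V);
  for (int t = 0; t < k; ++t) {
    const double denom = 2.0 * n_t[t] + Vbeta;
    for (int w = 0; w < V; ++w)
      phi(t, w) = (n_wt[(size_t)w * k + t] + beta) / denom;
  }
  NumericVector theta(k);
  for (int t = 0; t < k; ++t)
    theta[t] = (n_t[t] + alpha) / ((double)N + k * alpha);

  return List::create(_["phi"] = phi, _["theta_global"] = theta,
                      _["z"] = IntegerVector(z.begin(), z.end()));
}
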