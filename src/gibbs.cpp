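#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <string>
using namespace Rcpp;

// Counter-based per-cell RNG streams: each cell owns an xorshift64* stream
// seeded from (master seed, FNV-1a hash of its cell id), and cells are always
// processed in lexicographic id order.  Results are therefore invariant to
// the column order of the input matrix.
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

static inline uint64_t fnv1a(const std::string &s) {
  uint64_t h = 0xcbf29ce484222325ULL;
  for (char c : s) {
    h ^= (uint64_t)(unsigned char)c;
    h *= 0x100000001b3ULL;
  }
  return h;
}

struct Stream {
  uint64_t s;
  explicit Stream(uint64_t seed) : s(seed ? seed : 0x853c49e6748fea9bULL) {}
  inline double unif() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return ((s * 0x2545F4914F6CDD1DULL) >> 11) * (1.0 / 9007199254740992.0);
  }
};

// counts: V genes x M cells, non-negative integers.
// init_z: optional list (one integer vector per cell, 0-based topics, token
// order = genes in row order with multiplicity) used for warm starts.
// [[Rcpp::export]]
List lda_gibbs_cpp(IntegerMatrix counts, int K,
                   NumericVector alpha, NumericVector beta,
                   int sweeps, int burn_in, int thin,
                   double seed, CharacterVector cell_ids,
                   Nullable<List> init_z = R_NilValue) {
  const int V = counts.nrow(), M = counts.ncol();
  if ((int)alpha.size() != K) stop("alpha must have length K");
  if ((int)beta.size() != V) stop("beta must have length V");

  // canonical processing order: lexicographic cell id (byte order)
  std::vector<std::string> ids(M);
  for (int d = 0; d < M; ++d) ids[d] = as<std::string>(cell_ids[d]);
  std::vector<int> ord(M);
  for (int d = 0; d < M; ++d) ord[d] = d;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return ids[a] < ids[b]; });

  // expand tokens
  std::vector<std::vector<int>> tok_w(M), tok_z(M);
  for (int d = 0; d < M; ++d) {
    int nd = 0;
    for (int w = 0; w < V; ++w) nd += counts(w, d);
    tok_w[d].reserve(nd); tok_z[d].resize(nd);
    for (int w = 0; w < V; ++w)
      for (int r = 0; r < counts(w, d); ++r) tok_w[d].push_back(w);
  }

  std::vector<Stream> rng;
  rng.reserve(M);
  uint64_t master = (uint64_t)seed;
  for (int d = 0; d < M; ++d)
    rng.emplace_back(splitmix64(master ^ splitmix64(fnv1a(ids[d]))));

  // count tables
  std::vector<double> n_dk((size_t)M * K, 0.0), n_kw((size_t)K * V, 0.0),
      n_k(K, 0.0), n_d(M, 0.0);

  bool have_init = init_z.isNotNull();
  List init;
  if (have_init) init = List(init_z);
  for (int di = 0; di < M; ++di) {
    int d = ord[di];
    const std::vector<int> &ws = tok_w[d];
    IntegerVector zi;
    if (have_init) zi = init[d];
    for (size_t i = 0; i < ws.size(); ++i) {
      int z;
      if (have_init) {
        z = zi[i];
        if (z < 0 || z >= K) stop("init assignment out of range");
      } else {
        z = (int)(rng[d].unif() * K);
        if (z == K) z = K - 1;
      }
      tok_z[d][i] = z;
      n_dk[(size_t)d * K + z] += 1.0;
      n_kw[(size_t)z * V + ws[i]] += 1.0;
      n_k[z] += 1.0;
      n_d[d] += 1.0;
    }
  }

  double sum_alpha = 0.0, sum_beta = 0.0, lg_alpha = 0.0, lg_beta = 0.0;
  for (int k = 0; k < K; ++k) { sum_alpha += alpha[k]; lg_alpha += R::lgammafn(alpha[k]); }
  for (int w = 0; w < V; ++w) { sum_beta += beta[w]; lg_beta += R::lgammafn(beta[w]); }

  NumericVector loglik(sweeps);
  NumericMatrix theta_acc(M, K), phi_acc(K, V);
  int n_samp = 0;
  std::vector<double> p(K);

  for (int s = 0; s < sweeps; ++s) {
    for (int di = 0; di < M; ++di) {
      int d = ord[di];
      Stream &st = rng[d];
      const std::vector<int> &ws = tok_w[d];
      std::vector<int> &zs = tok_z[d];
      double *nd = &n_dk[(size_t)d * K];
      for (size_t i = 0; i < ws.size(); ++i) {
        int w = ws[i], z = zs[i];
        nd[z] -= 1.0; n_kw[(size_t)z * V + w] -= 1.0; n_k[z] -= 1.0;
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          p[k] = (nd[k] + alpha[k]) * (n_kw[(size_t)k * V + w] + beta[w]) /
                 (n_k[k] + sum_beta);
          tot += p[k];
        }
        double u = st.unif() * tot, acc = 0.0;
        int znew = K - 1;
        for (int k = 0; k < K; ++k) { acc += p[k]; if (u < acc) { znew = k; break; } }
        zs[i] = znew;
        nd[znew] += 1.0; n_kw[(size_t)znew * V + w] += 1.0; n_k[znew] += 1.0;
      }
    }
    // complete-data log likelihood log p(w, z | alpha, beta)
    double ll = M * (R::lgammafn(sum_alpha) - lg_alpha) +
                K * (R::lgammafn(sum_beta) - lg_beta);
    for (int d = 0; d < M; ++d) {
      for (int k = 0; k < K; ++k) ll += R::lgammafn(n_dk[(size_t)d * K + k] + alpha[k]);
      ll -= R::lgammafn(n_d[d] + sum_alpha);
    }
    for (int k = 0; k < K; ++k) {
      for (int w = 0; w < V; ++w) ll += R::lgammafn(n_kw[(size_t)k * V + w] + beta[w]);
      ll -= R::lgammafn(n_k[k] + sum_beta);
    }
    loglik[s] = ll;

    if (s >= burn_in && (s - burn_in) % thin == 0) {
      ++n_samp;
      for (int d = 0; d < M; ++d)
        for (int k = 0; k < K; ++k)
          theta_acc(d, k) += (n_dk[(size_t)d * K + k] + alpha[k]) / (n_d[d] + sum_alpha);
      for (int k = 0; k < K; ++k)
        for (int w = 0; w < V; ++w)
          phi_acc(k, w) += (n_kw[(size_t)k * V + w] + beta[w]) / (n_k[k] + sum_beta);
    }
    if (s % 64 == 0) Rcpp::checkUserInterrupt();
  }

  // exact row renormalisation of the posterior means
  NumericMatrix theta(M, K), phi(K, V);
  for (int d = 0; d < M; ++d) {
    double rs = 0.0;
    for (int k = 0; k < K; ++k) rs += theta_acc(d, k);
    for (int k = 0; k < K; ++k) theta(d, k) = theta_acc(d, k) / rs;
  }
  for (int k = 0; k < K; ++k) {
    double rs = 0.0;
    for (int w = 0; w < V; ++w) rs += phi_acc(k, w);
    for (int w = 0; w < V; ++w) phi(k, w) = phi_acc(k, w) / rs;
  }

  List zs_out(M);
  for (int d = 0; d < M; ++d) zs_out[d] = wrap(tok_z[d]);

  return List::create(_["theta"] = theta, _["phi"] = phi,
                      _["loglik"] = loglik, _["assignments"] = zs_out,
                      _["n_samples"] = n_samp);
}

// Token-level multinomial draws for the synthetic generator, using the same
// per-cell streams so fixtures are bit-identical across platforms.
// theta: M x K, phi: K x V.  Returns V x M counts plus per-cell topic tallies.
// [[Rcpp::export]]
List lda_generate_cpp(NumericMatrix theta, NumericMatrix phi,
                      int tokens_per_cell, double seed,
                      CharacterVector cell_ids) {
  const int M = theta.nrow(), K = theta.ncol(), V = phi.ncol();
  IntegerMatrix counts(V, M);
  IntegerMatrix topic_counts(M, K);
  uint64_t master = (uint64_t)seed;
  for (int d = 0; d < M; ++d) {
    Stream st(splitmix64(master ^ splitmix64(fnv1a(as<std::string>(cell_ids[d])))));
    for (int t = 0; t < tokens_per_cell; ++t) {
      double u = st.unif(), acc = 0.0;
      int k = K - 1;
      for (int j = 0; j < K; ++j) { acc += theta(d, j); if (u < acc) { k = j; break; } }
      u = st.unif(); acc = 0.0;
      int w = V - 1;
      for (int j = 0; j < V; ++j) { acc += phi(k, j); if (u < acc) { w = j; break; } }
      counts(w, d) += 1;
      topic_counts(d, k) += 1;
    }
  }
  return List::create(_["counts"] = counts, _["topic_counts"] = topic_counts);
}
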