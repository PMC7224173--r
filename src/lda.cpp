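// Latent Dirichlet allocation by collapsed Gibbs sampling, used for the
// topic-feature classifier of the extrinsic evaluation. The topic model is
// fitted on the generation-training corpus; held-out documents are folded in
// against the fixed topic-word counts. All sampling is driven by one
// std::mt19937 stream so results are reproducible from the seed.

#include <Rcpp.h>
#include <random>
using namespace Rcpp;

static int sample_cat(const std::vector<double>& w, std::mt19937& rng) {
  double tot = 0.0;
  for (double v : w) tot += v;
  std::uniform_real_distribution<double> unif(0.0, tot);
  double u = unif(rng);
  double acc = 0.0;
  for (size_t k = 0; k < w.size(); ++k) {
    acc += w[k];
    if (u <= acc) return (int)k;
  }
  return (int)w.size() - 1;
}

// docs: list of 1-based token-index vectors
// [[Rcpp::export]]
List cpp_lda_fit(List docs, int V, int K, double alpha, double beta,
                 int iters, int seed) {
  int D = docs.size();
  std::vector<std::vector<int>> w(D);
  for (int d = 0; d < D; ++d) {
    IntegerVector v = docs[d];
    w[d].assign(v.begin(), v.end());
    for (int& t : w[d]) --t;
  }
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<std::vector<int>> z(D);
  NumericMatrix nkw(K, V);
  std::vector<double> nk(K, 0.0);
  NumericMatrix ndk(D, K);
  std::uniform_int_distribution<int> topic0(0, K - 1);
  for (int d = 0; d < D; ++d) {
    z[d].resize(w[d].size());
    for (size_t i = 0; i < w[d].size(); ++i) {
      int k = topic0(rng);
      z[d][i] = k;
      nkw(k, w[d][i]) += 1.0;
      nk[k] += 1.0;
      ndk(d, k) += 1.0;
    }
  }
  std::vector<double> prob(K);
  for (int it = 0; it < iters; ++it) {
    for (int d = 0; d < D; ++d) {
      for (size_t i = 0; i < w[d].size(); ++i) {
        int t = w[d][i], k = z[d][i];
        nkw(k, t) -= 1.0; nk[k] -= 1.0; ndk(d, k) -= 1.0;
        for (int kk = 0; kk < K; ++kk) {
          prob[kk] = (nkw(kk, t) + beta) / (nk[kk] + beta * V) *
                     (ndk(d, kk) + alpha);
        }
        k = sample_cat(prob, rng);
        z[d][i] = k;
        nkw(k, t) += 1.0; nk[k] += 1.0; ndk(d, k) += 1.0;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  // posterior topic-word weights (phi) and training-document mixtures
  NumericMatrix phi(K, V);
  for (int k = 0; k < K; ++k) {
    for (int t = 0; t < V; ++t) phi(k, t) = (nkw(k, t) + beta) / (nk[k] + beta * V);
  }
  NumericMatrix theta(D, K);
  for (int d = 0; d < D; ++d) {
    double tot = (double)w[d].size() + alpha * K;
    for (int k = 0; k < K; ++k) theta(d, k) = (ndk(d, k) + alpha) / tot;
  }
  return List::create(_["phi"] = phi, _["theta"] = theta);
}

// fold in new documents against fixed phi
// [[Rcpp::export]]
NumericMatrix cpp_lda_infer(List docs, NumericMatrix phi, double alpha,
                            int iters, int seed) {
  int D = docs.size(), K = phi.nrow();
  std::mt19937 rng(static_cast<unsigned>(seed) + 1337u);
  NumericMatrix theta(D, K);
  std::uniform_int_distribution<int> topic0(0, K - 1);
  std::vector<double> prob(K);
  for (int d = 0; d < D; ++d) {
    IntegerVector v = docs[d];
    std::vector<int> w(v.begin(), v.end());
    for (int& t : w) --t;
    std::vector<int> z(w.size());
    std::vector<double> ndk(K, 0.0);
    for (size_t i = 0; i < w.size(); ++i) {
      z[i] = topic0(rng);
      ndk[z[i]] += 1.0;
    }
    for (int it = 0; it < iters; ++it) {
      for (size_t i = 0; i < w.size(); ++i) {
        int t = w[i], k = z[i];
        ndk[k] -= 1.0;
        for (int kk = 0; kk < K; ++kk) {
          prob[kk] = phi(kk, t) * (ndk[kk] + alpha);
        }
        k = sample_cat(prob, rng);
        z[i] = k;
        ndk[k] += 1.0;
      }
    }
    double tot = (double)w.size() + alpha * K;
    for (int k = 0; k < K; ++k) theta(d, k) = (ndk[k] + alpha) / tot;
    Rcpp::checkUserInterrupt();
  }
  return theta;
}
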