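// Deterministic single-threaded skip-gram with negative sampling for small
// code-co-occurrence corpora. Sentences are short (<= 5 codes), so no
// subsampling of frequent words and no dynamic window shrinking are used:
// every pair within the window is a training example, which keeps runs
// exactly reproducible for a fixed seed.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

// splitmix64: small, well-mixed deterministic generator
struct Rng {
  uint64_t state;
  explicit Rng(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix sgns_train(List sentences, int vocab, NumericVector counts,
                         int dim, int window, int epochs, int negative,
                         double alpha0, double min_alpha, int seed) {
  if (vocab < 2) stop("need at least two codes to train embeddings");
  Rng rng(static_cast<uint64_t>(seed) * 0x9e3779b97f4a7c15ULL + 1ULL);

  // unigram^(3/4) cumulative table for negative sampling
  std::vector<double> cum(vocab);
  double tot = 0.0;
  for (int i = 0; i < vocab; ++i) {
    tot += std::pow(counts[i], 0.75);
    cum[i] = tot;
  }
  for (int i = 0; i < vocab; ++i) cum[i] /= tot;

  std::vector<double> syn0(static_cast<size_t>(vocab) * dim);
  std::vector<double> syn1(static_cast<size_t>(vocab) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  // pre-extract sentences
  std::vector<std::vector<int>> sents;
  sents.reserve(sentences.size());
  long long total_pos = 0;
  for (int s = 0; s < sentences.size(); ++s) {
    IntegerVector sv = sentences[s];
    std::vector<int> v(sv.begin(), sv.end());
    for (int w : v)
      if (w < 0 || w >= vocab) stop("sentence token out of vocabulary range");
    total_pos += v.size();
    sents.push_back(std::move(v));
  }
  if (total_pos == 0) stop("empty corpus");

  const long long total_steps = total_pos * epochs;
  long long step = 0;
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (const auto& sent : sents) {
      const int len = static_cast<int>(sent.size());
      for (int i = 0; i < len; ++i, ++step) {
        double lr = alpha0 * (1.0 - static_cast<double>(step) / total_steps);
        if (lr < min_alpha) lr = min_alpha;
        const int center = sent[i];
        double* v0 = &syn0[static_cast<size_t>(center) * dim];
        const int lo = i - window < 0 ? 0 : i - window;
        const int hi = i + window >= len ? len - 1 : i + window;
        for (int j = lo; j <= hi; ++j) {
          if (j == i) continue;
          const int context = sent[j];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int nmb = 0; nmb <= negative; ++nmb) {
            int target;
            double label;
            if (nmb == 0) {
              target = context;
              label = 1.0;
            } else {
              const double u = rng.unif();
              target = static_cast<int>(
                  std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
              if (target >= vocab) target = vocab - 1;
              if (target == context) continue;
              label = 0.0;
            }
            double* v1 = &syn1[static_cast<size_t>(target) * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += v0[d] * v1[d];
            const double g = (label - sigmoid(dot)) * lr;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * v1[d];
              v1[d] += g * v0[d];
            }
          }
          for (int d = 0; d < dim; ++d) v0[d] += grad[d];
        }
      }
    }
  }

  NumericMatrix out(vocab, dim);
  for (int i = 0; i < vocab; ++i)
    for (int d = 0; d < dim; ++d)
      out(i, d) = syn0[static_cast<size_t>(i) * dim + d];
  return out;
}
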