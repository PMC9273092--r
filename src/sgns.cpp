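#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Skip-gram with negative sampling, single-threaded and fully deterministic
// given `seed`. Matches the classic word2vec training scheme: dynamic window,
// unigram^(3/4) negative-sampling table, linearly decaying learning rate.

namespace {

struct XorShift64 {
  uint64_t state;
  explicit XorShift64(uint64_t seed) : state(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t x = state;
    x ^= x << 13;
    x ^= x >> 7;
    x ^= x << 17;
    state = x;
    return x;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  uint64_t below(uint64_t n) { return next() % n; }
};

inline double sigmoid(double x) {
  if (x > 6.0) return 1.0;
  if (x < -6.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

} // namespace

// corpus: list of integer vectors of 0-based vocabulary ids (negatives ignored)
// counts: vocabulary frequencies, length V
// [[Rcpp::export(name = ".sgns_train")]]
NumericMatrix sgns_train(List corpus, IntegerVector counts, int dim, int window,
                         int negative, int epochs, double alpha, int seed) {
  const int V = counts.size();
  if (V == 0) stop("empty vocabulary");

  // negative-sampling table (unigram distribution to the 3/4 power)
  const int table_size = 1 << 20;
  std::vector<int> table(table_size);
  {
    double total = 0.0;
    for (int i = 0; i < V; ++i) total += std::pow((double)counts[i], 0.75);
    double cum = std::pow((double)counts[0], 0.75) / total;
    int w = 0;
    for (int i = 0; i < table_size; ++i) {
      table[i] = w;
      if ((double)(i + 1) / table_size > cum && w < V - 1) {
        ++w;
        cum += std::pow((double)counts[w], 0.75) / total;
      }
    }
  }

  XorShift64 rng((uint64_t)seed * 2654435761ULL + 1ULL);

  std::vector<double> syn0((size_t)V * dim);
  std::vector<double> syn1((size_t)V * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  // total positions, for the learning-rate schedule
  long long total_words = 0;
  const int S = corpus.size();
  for (int s = 0; s < S; ++s) total_words += Rf_length(VECTOR_ELT(corpus, s));
  total_words *= epochs;
  if (total_words == 0) stop("empty corpus");

  const double min_alpha = alpha * 1e-4;
  long long processed = 0;
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < S; ++s) {
      IntegerVector sent = corpus[s];
      const int n = sent.size();
      for (int pos = 0; pos < n; ++pos) {
        ++processed;
        int w = sent[pos];
        if (w < 0 || w >= V) continue;
        double lr = alpha * (1.0 - (double)processed / (total_words + 1));
        if (lr < min_alpha) lr = min_alpha;
        int b = (int)rng.below((uint64_t)window); // dynamic window shrink
        for (int off = b - window; off <= window - b; ++off) {
          if (off == 0) continue;
          int cpos = pos + off;
          if (cpos < 0 || cpos >= n) continue;
          int c = sent[cpos];
          if (c < 0 || c >= V) continue;
          // predict context c from center w
          double *vw = &syn0[(size_t)w * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int target;
            double label;
            if (d == 0) {
              target = c;
              label = 1.0;
            } else {
              target = table[rng.below((uint64_t)table_size)];
              if (target == c) continue;
              label = 0.0;
            }
            double *vt = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int k = 0; k < dim; ++k) dot += vw[k] * vt[k];
            double g = (label - sigmoid(dot)) * lr;
            for (int k = 0; k < dim; ++k) {
              grad[k] += g * vt[k];
              vt[k] += g * vw[k];
            }
          }
          for (int k = 0; k < dim; ++k) vw[k] += grad[k];
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(V, dim);
  for (int i = 0; i < V; ++i)
    for (int k = 0; k < dim; ++k) out(i, k) = syn0[(size_t)i * dim + k];
  return out;
}
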