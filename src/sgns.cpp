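#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Self-contained xorshift64* RNG so embedding training is bit-reproducible
// across platforms independently of R's RNG state.
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling over pre-tokenized sentences.
// sentences: list of 0-based integer token-id vectors; counts: token counts
// for the unigram^0.75 negative-sampling table.
// [[Rcpp::export(name = ".sgns_train")]]
NumericMatrix sgns_train(List sentences, int vocab_size, int dim, int window,
                         int epochs, int negative, double alpha,
                         double min_alpha, NumericVector counts,
                         double seed) {
  XorShift rng(static_cast<uint64_t>(seed));

  std::vector<double> cum(vocab_size);
  double tot = 0.0;
  for (int v = 0; v < vocab_size; ++v) {
    tot += std::pow(counts[v], 0.75);
    cum[v] = tot;
  }

  std::vector<double> win(static_cast<size_t>(vocab_size) * dim);
  std::vector<double> wout(static_cast<size_t>(vocab_size) * dim, 0.0);
  for (size_t i = 0; i < win.size(); ++i)
    win[i] = (rng.unif() - 0.5) / dim;

  long long total_centers = 0;
  int n_sent = sentences.size();
  std::vector<std::vector<int> > sents(n_sent);
  for (int s = 0; s < n_sent; ++s) {
    IntegerVector iv = sentences[s];
    sents[s] = std::vector<int>(iv.begin(), iv.end());
    total_centers += iv.size();
  }
  long long total_steps = total_centers * static_cast<long long>(epochs);
  long long step = 0;

  std::vector<double> grad(dim);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_sent; ++s) {
      const std::vector<int>& sent = sents[s];
      int n = static_cast<int>(sent.size());
      for (int i = 0; i < n; ++i, ++step) {
        double lr = alpha - (alpha - min_alpha) * (static_cast<double>(step) / total_steps);
        if (lr < min_alpha) lr = min_alpha;
        int center = sent[i];
        double* vc = &win[static_cast<size_t>(center) * dim];
        int lo = i - window < 0 ? 0 : i - window;
        int hi = i + window >= n ? n - 1 : i + window;
        for (int j = lo; j <= hi; ++j) {
          if (j == i) continue;
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int target; double label;
            if (neg == 0) { target = sent[j]; label = 1.0; }
            else {
              double r = rng.unif() * tot;
              int loidx = 0, hiidx = vocab_size - 1;
              while (loidx < hiidx) {
                int mid = (loidx + hiidx) / 2;
                if (cum[mid] < r) loidx = mid + 1; else hiidx = mid;
              }
              target = loidx; label = 0.0;
              if (target == sent[j]) continue;
            }
            double* vt = &wout[static_cast<size_t>(target) * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += vc[d] * vt[d];
            double g = (label - sigmoid(dot)) * lr;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * vt[d];
              vt[d] += g * vc[d];
            }
          }
          for (int d = 0; d < dim; ++d) vc[d] += grad[d];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int v = 0; v < vocab_size; ++v)
    for (int d = 0; d < dim; ++d)
      out(v, d) = win[static_cast<size_t>(v) * dim + d];
  return out;
}
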