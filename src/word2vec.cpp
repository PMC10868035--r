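// Minimal single-threaded word2vec (SGNS / CBOW) trainer for medical-code
// corpora. Sentences are visits (unordered code sets); codes are shuffled
// within each sentence every epoch, so the context window is order-free in
// expectation. All randomness comes from an internal xorshift generator
// seeded from R, making training bit-reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

inline uint64_t xorshift64(uint64_t &s) {
  s ^= s << 13;
  s ^= s >> 7;
  s ^= s << 17;
  return s;
}

inline double runif01(uint64_t &s) {
  return static_cast<double>(xorshift64(s) >> 11) * (1.0 / 9007199254740992.0);
}

inline int runif_int(uint64_t &s, int n) {
  return static_cast<int>(runif01(s) * n) % n;
}

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// draw from the unigram^0.75 table via inverse CDF (binary search)
inline int sample_negative(uint64_t &s, const std::vector<double> &cum) {
  double u = runif01(s) * cum.back();
  int lo = 0, hi = static_cast<int>(cum.size()) - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix w2v_train_cpp(List sentences, int vocab_size, int dim,
                            int window, int negative, int epochs, double lr,
                            std::string method, NumericVector counts,
                            double seed) {
  const bool cbow = (method == "cbow");
  uint64_t rng = static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL;
  for (int i = 0; i < 8; ++i) xorshift64(rng);

  const int n_sent = sentences.size();
  std::vector<std::vector<int>> corpus(n_sent);
  long long total_words = 0;
  for (int i = 0; i < n_sent; ++i) {
    IntegerVector sv = sentences[i];
    corpus[i].assign(sv.begin(), sv.end());
    total_words += sv.size();
  }

  std::vector<double> cum(vocab_size);
  double acc = 0.0;
  for (int v = 0; v < vocab_size; ++v) {
    acc += std::pow(std::max(counts[v], 0.0), 0.75);
    cum[v] = acc;
  }
  if (acc <= 0.0) stop("empty corpus: no observed codes");

  std::vector<double> syn0(static_cast<size_t>(vocab_size) * dim);
  std::vector<double> syn1(static_cast<size_t>(vocab_size) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i) {
    syn0[i] = (runif01(rng) - 0.5) / dim;
  }

  std::vector<double> neu1(dim), neu1e(dim);
  const long long schedule = std::max(1LL, total_words * epochs);
  long long processed = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int si = 0; si < n_sent; ++si) {
      std::vector<int> &sent = corpus[si];
      const int len = static_cast<int>(sent.size());
      if (len == 0) continue;
      // Fisher-Yates shuffle: codes within a visit carry no order
      for (int a = len - 1; a > 0; --a) {
        int b = runif_int(rng, a + 1);
        std::swap(sent[a], sent[b]);
      }
      for (int pos = 0; pos < len; ++pos) {
        double alpha =
            lr * std::max(1e-4, 1.0 - static_cast<double>(processed) / schedule);
        ++processed;
        const int lo = std::max(0, pos - window);
        const int hi = std::min(len - 1, pos + window);
        const int center = sent[pos];

        if (cbow) {
          int nctx = 0;
          std::fill(neu1.begin(), neu1.end(), 0.0);
          for (int c = lo; c <= hi; ++c) {
            if (c == pos) continue;
            const double *v0 = &syn0[static_cast<size_t>(sent[c]) * dim];
            for (int k = 0; k < dim; ++k) neu1[k] += v0[k];
            ++nctx;
          }
          if (nctx == 0) continue;
          for (int k = 0; k < dim; ++k) neu1[k] /= nctx;
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int target;
            double label;
            if (neg == 0) {
              target = center;
              label = 1.0;
            } else {
              target = sample_negative(rng, cum);
              int tries = 0;
              while (target == center && ++tries < 10) {
                target = sample_negative(rng, cum);
              }
              if (target == center) continue;
              label = 0.0;
            }
            double *v1 = &syn1[static_cast<size_t>(target) * dim];
            double f = 0.0;
            for (int k = 0; k < dim; ++k) f += neu1[k] * v1[k];
            const double g = (label - sigmoid(f)) * alpha;
            for (int k = 0; k < dim; ++k) {
              neu1e[k] += g * v1[k];
              v1[k] += g * neu1[k];
            }
          }
          for (int c = lo; c <= hi; ++c) {
            if (c == pos) continue;
            double *v0 = &syn0[static_cast<size_t>(sent[c]) * dim];
            for (int k = 0; k < dim; ++k) v0[k] += neu1e[k];
          }
        } else {  // SGNS: center predicts each context word
          for (int c = lo; c <= hi; ++c) {
            if (c == pos) continue;
            const int context = sent[c];
            double *v0 = &syn0[static_cast<size_t>(center) * dim];
            std::fill(neu1e.begin(), neu1e.end(), 0.0);
            for (int neg = 0; neg <= negative; ++neg) {
              int target;
              double label;
              if (neg == 0) {
                target = context;
                label = 1.0;
              } else {
                target = sample_negative(rng, cum);
                int tries = 0;
                while (target == context && ++tries < 10) {
                  target = sample_negative(rng, cum);
                }
                if (target == context) continue;
                label = 0.0;
              }
              double *v1 = &syn1[static_cast<size_t>(target) * dim];
              double f = 0.0;
              for (int k = 0; k < dim; ++k) f += v0[k] * v1[k];
              const double g = (label - sigmoid(f)) * alpha;
              for (int k = 0; k < dim; ++k) {
                neu1e[k] += g * v1[k];
                v1[k] += g * v0[k];
              }
            }
            for (int k = 0; k < dim; ++k) v0[k] += neu1e[k];
          }
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int v = 0; v < vocab_size; ++v) {
    for (int k = 0; k < dim; ++k) {
      out(v, k) = syn0[static_cast<size_t>(v) * dim + k];
    }
  }
  return out;
}
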