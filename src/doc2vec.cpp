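// Paragraph-vector (distributed memory) embedding trainer with negative
// sampling. Single worker, explicit seed: training and inference are exactly
// reproducible. Word ids arrive 0-based; -1 marks an out-of-vocabulary token.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline std::uint64_t xorshift64(std::uint64_t &s) {
  s ^= s << 13;
  s ^= s >> 7;
  s ^= s << 17;
  return s;
}

static inline double runif01(std::uint64_t &s) {
  return (double)(xorshift64(s) >> 11) * (1.0 / 9007199254740992.0);
}

static inline double sigmoid_clip(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Cumulative unigram^0.75 table for negative sampling.
static std::vector<double> neg_table(const NumericVector &counts) {
  std::vector<double> cum(counts.size());
  double acc = 0.0;
  for (int i = 0; i < counts.size(); ++i) {
    acc += std::pow(counts[i], 0.75);
    cum[i] = acc;
  }
  for (double &c : cum) c /= acc;
  return cum;
}

static inline int sample_neg(const std::vector<double> &cum, std::uint64_t &s) {
  double u = runif01(s);
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// One PV-DM update at position t of a document. The input is the mean of the
// context word vectors and the paragraph vector; the centre word is the
// positive target against `negative` sampled negatives. Returns gradient
// applied to the shared input mean; the caller distributes it.
static void pvdm_position(const std::vector<int> &doc, int t, int window,
                          int negative, double lr,
                          std::vector<double> &Wv, std::vector<double> &Ov,
                          double *dvec, int dim, int vocab,
                          const std::vector<double> &cum, std::uint64_t &rng,
                          bool update_words) {
  int w = doc[t];
  if (w < 0) return;
  std::vector<int> ctx;
  int T = (int)doc.size();
  for (int j = t - window; j <= t + window; ++j) {
    if (j == t || j < 0 || j >= T) continue;
    if (doc[j] >= 0) ctx.push_back(doc[j]);
  }
  int denom = (int)ctx.size() + 1;
  std::vector<double> h(dim, 0.0), gh(dim, 0.0);
  for (int d = 0; d < dim; ++d) h[d] = dvec[d];
  for (int c : ctx)
    for (int d = 0; d < dim; ++d) h[d] += Wv[(size_t)c * dim + d];
  for (int d = 0; d < dim; ++d) h[d] /= denom;

  for (int k = 0; k <= negative; ++k) {
    int target;
    double label;
    if (k == 0) {
      target = w;
      label = 1.0;
    } else {
      target = sample_neg(cum, rng);
      if (target == w) continue;
      label = 0.0;
    }
    double *ov = &Ov[(size_t)target * dim];
    double f = 0.0;
    for (int d = 0; d < dim; ++d) f += h[d] * ov[d];
    double g = (label - sigmoid_clip(f)) * lr;
    for (int d = 0; d < dim; ++d) {
      gh[d] += g * ov[d];
      ov[d] += g * h[d];
    }
  }
  for (int d = 0; d < dim; ++d) dvec[d] += gh[d] / denom;
  if (update_words) {
    for (int c : ctx) {
      double *wv = &Wv[(size_t)c * dim];
      for (int d = 0; d < dim; ++d) wv[d] += gh[d] / denom;
    }
  }
}

// [[Rcpp::export(name = ".pvdm_train")]]
List pvdm_train(List docs, NumericVector vocab_counts, int dim, int window,
                int epochs, int negative, double alpha, double alpha_min,
                double seed) {
  int vocab = vocab_counts.size();
  int ndocs = docs.size();
  std::uint64_t rng = (std::uint64_t)seed * 2654435761ULL + 1ULL;

  std::vector<double> Wv((size_t)vocab * dim), Ov((size_t)vocab * dim, 0.0);
  std::vector<double> Dv((size_t)ndocs * dim);
  for (auto &x : Wv) x = (runif01(rng) - 0.5) / dim;
  for (auto &x : Dv) x = (runif01(rng) - 0.5) / dim;

  std::vector<std::vector<int>> D(ndocs);
  long total_pos = 0;
  for (int i = 0; i < ndocs; ++i) {
    IntegerVector v = docs[i];
    D[i].assign(v.begin(), v.end());
    total_pos += v.size();
  }
  std::vector<double> cum = neg_table(vocab_counts);

  long seen = 0;
  long total = total_pos * (long)epochs;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = 0; i < ndocs; ++i) {
      double *dvec = &Dv[(size_t)i * dim];
      int T = (int)D[i].size();
      for (int t = 0; t < T; ++t) {
        double lr = alpha - (alpha - alpha_min) * ((double)seen / (double)total);
        pvdm_position(D[i], t, window, negative, lr, Wv, Ov, dvec, dim, vocab,
                      cum, rng, true);
        ++seen;
      }
    }
  }

  NumericMatrix word(vocab, dim), out(vocab, dim), dvecs(ndocs, dim);
  for (int i = 0; i < vocab; ++i)
    for (int d = 0; d < dim; ++d) {
      word(i, d) = Wv[(size_t)i * dim + d];
      out(i, d) = Ov[(size_t)i * dim + d];
    }
  for (int i = 0; i < ndocs; ++i)
    for (int d = 0; d < dim; ++d) dvecs(i, d) = Dv[(size_t)i * dim + d];
  return List::create(_["word"] = word, _["out"] = out, _["doc"] = dvecs);
}

// [[Rcpp::export(name = ".pvdm_infer")]]
NumericVector pvdm_infer(IntegerVector doc, NumericMatrix word,
                         NumericMatrix out, NumericVector vocab_counts,
                         int window, int epochs, int negative, double alpha,
                         double alpha_min, double seed) {
  int dim = word.ncol();
  int vocab = word.nrow();
  std::uint64_t rng = (std::uint64_t)seed * 2654435761ULL + 1ULL;

  std::vector<double> Wv((size_t)vocab * dim), Ov((size_t)vocab * dim);
  for (int i = 0; i < vocab; ++i)
    for (int d = 0; d < dim; ++d) {
      Wv[(size_t)i * dim + d] = word(i, d);
      Ov[(size_t)i * dim + d] = out(i, d);
    }
  std::vector<double> dvec(dim);
  for (auto &x : dvec) x = (runif01(rng) - 0.5) / dim;

  std::vector<int> D(doc.begin(), doc.end());
  std::vector<double> cum = neg_table(vocab_counts);
  long total = (long)D.size() * (long)epochs;
  long seen = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int t = 0; t < (int)D.size(); ++t) {
      double lr = alpha - (alpha - alpha_min) * ((double)seen / (double)total);
      pvdm_position(D, t, window, negative, lr, Wv, Ov, dvec.data(), dim,
                    vocab, cum, rng, false);
      ++seen;
    }
  }
  return NumericVector(dvec.begin(), dvec.end());
}
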