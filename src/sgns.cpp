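// Skip-gram with negative sampling over word + hashed character-ngram
// (subword) vectors. Single-threaded and fully deterministic under the
// supplied seed; scale target is desk-sized recipe corpora, not web-scale
// text, so no hierarchical softmax, hogwild threading or frequent-word
// subsampling.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// [[Rcpp::export]]
List cpp_train_sgns(List docs, int n_words, List word_ngrams, int n_buckets,
                    int dim, int window, int epochs, int negative,
                    double lr, NumericVector unigram_probs, int seed) {
  const int n_rows = n_words + n_buckets;
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // input rows: words then subword buckets; output rows: words only
  std::vector<double> in(static_cast<size_t>(n_rows) * dim);
  std::vector<double> out(static_cast<size_t>(n_words) * dim, 0.0);
  const double span = 0.5 / dim;
  for (auto &v : in) v = (unif(rng) * 2.0 - 1.0) * span;

  // cumulative unigram^0.75 table for negative sampling
  std::vector<double> cum(n_words);
  double acc = 0.0;
  for (int w = 0; w < n_words; ++w) { acc += unigram_probs[w]; cum[w] = acc; }
  for (int w = 0; w < n_words; ++w) cum[w] /= acc;
  auto sample_negative = [&]() {
    double u = unif(rng);
    return static_cast<int>(std::lower_bound(cum.begin(), cum.end(), u) -
                            cum.begin());
  };

  // per-word contributing input rows (word id + its ngram buckets)
  std::vector<std::vector<int>> rows(n_words);
  for (int w = 0; w < n_words; ++w) {
    IntegerVector g = word_ngrams[w];
    rows[w].reserve(g.size() + 1);
    rows[w].push_back(w);
    for (int j = 0; j < g.size(); ++j) rows[w].push_back(n_words + g[j]);
  }

  long long total_tokens = 0;
  for (int d = 0; d < docs.size(); ++d)
    total_tokens += static_cast<IntegerVector>(docs[d]).size();
  const long long total_work = total_tokens * static_cast<long long>(epochs);
  long long done = 0;

  std::vector<double> hidden(dim), grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int d = 0; d < docs.size(); ++d) {
      IntegerVector doc = docs[d];
      const int n = doc.size();
      for (int t = 0; t < n; ++t) {
        ++done;
        double alpha = lr * (1.0 - static_cast<double>(done) / (total_work + 1));
        if (alpha < lr * 1e-4) alpha = lr * 1e-4;
        int center = doc[t];
        const std::vector<int> &crows = rows[center];
        const double inv = 1.0 / crows.size();
        // composed center representation (mean of contributing rows)
        for (int k = 0; k < dim; ++k) hidden[k] = 0.0;
        for (int r : crows) {
          const double *vr = &in[static_cast<size_t>(r) * dim];
          for (int k = 0; k < dim; ++k) hidden[k] += vr[k];
        }
        for (int k = 0; k < dim; ++k) hidden[k] *= inv;

        int b = 1 + static_cast<int>(unif(rng) * window);
        if (b > window) b = window;
        for (int off = -b; off <= b; ++off) {
          if (off == 0) continue;
          int pos = t + off;
          if (pos < 0 || pos >= n) continue;
          int context = doc[pos];
          for (int k = 0; k < dim; ++k) grad[k] = 0.0;
          for (int s = 0; s <= negative; ++s) {
            int target; double label;
            if (s == 0) { target = context; label = 1.0; }
            else {
              target = sample_negative();
              if (target == context) continue;
              label = 0.0;
            }
            double *vo = &out[static_cast<size_t>(target) * dim];
            double dot = 0.0;
            for (int k = 0; k < dim; ++k) dot += hidden[k] * vo[k];
            double g = (label - sigmoid(dot)) * alpha;
            for (int k = 0; k < dim; ++k) {
              grad[k] += g * vo[k];
              vo[k] += g * hidden[k];
            }
          }
          // distribute gradient over contributing input rows
          for (int r : crows) {
            double *vr = &in[static_cast<size_t>(r) * dim];
            for (int k = 0; k < dim; ++k) vr[k] += grad[k] * inv;
          }
        }
      }
    }
  }

  NumericMatrix in_mat(n_rows, dim), out_mat(n_words, dim);
  for (int r = 0; r < n_rows; ++r)
    for (int k = 0; k < dim; ++k)
      in_mat(r, k) = in[static_cast<size_t>(r) * dim + k];
  for (int r = 0; r < n_words; ++r)
    for (int k = 0; k < dim; ++k)
      out_mat(r, k) = out[static_cast<size_t>(r) * dim + k];
  return List::create(_["input"] = in_mat, _["output"] = out_mat);
}
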