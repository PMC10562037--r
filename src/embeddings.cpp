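// Deterministic single-threaded trainers for the embedding model kinds:
// skip-gram with negative sampling (word2vec; with optional subword units
// for the fasttext kind), PV-DBOW document vectors (doc2vec), and
// AdaGrad factorization of a weighted co-occurrence matrix (glove).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <map>
#include <vector>

using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 88172645463325252ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17; return s;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return static_cast<int>(next() % n); }
};

double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

std::vector<int> build_neg_table(const std::vector<double>& counts,
                                 int table_size) {
  std::vector<int> table(table_size);
  double total = 0.0;
  for (double c : counts) total += std::pow(c, 0.75);
  int i = 0;
  double cum = std::pow(counts[0], 0.75) / total;
  for (int k = 0; k < table_size; ++k) {
    table[k] = i;
    if ((k + 1.0) / table_size > cum && i < (int)counts.size() - 1) {
      ++i;
      cum += std::pow(counts[i], 0.75) / total;
    }
  }
  return table;
}

std::vector<std::vector<int>> as_sentences(const List& sents) {
  std::vector<std::vector<int>> out(sents.size());
  for (int i = 0; i < sents.size(); ++i) {
    IntegerVector s = sents[i];
    out[i].assign(s.begin(), s.end());
  }
  return out;
}

}  // namespace

// Skip-gram with negative sampling; when `subwords` is non-empty, the
// input representation of word w is the mean of its own vector and its
// subword n-gram vectors (fasttext kind). Word ids and n-gram ids are
// 0-based.
// [[Rcpp::export]]
List train_sgns_cpp(List sents, int vocab_size, int dim, int window,
                    int epochs, int negative, double alpha, int seed,
                    List subwords, int n_ngrams) {
  std::vector<std::vector<int>> S = as_sentences(sents);
  bool use_sub = subwords.size() > 0;
  std::vector<std::vector<int>> sub;
  if (use_sub) {
    sub.resize(subwords.size());
    for (int i = 0; i < subwords.size(); ++i) {
      IntegerVector g = subwords[i];
      sub[i].assign(g.begin(), g.end());
    }
  }
  XorShift rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);
  std::vector<double> counts(vocab_size, 0.0);
  long long total_tokens = 0;
  for (auto& s : S) { total_tokens += s.size(); for (int w : s) counts[w] += 1.0; }
  std::vector<int> neg_table = build_neg_table(counts, 100000);

  int n_in = vocab_size + (use_sub ? n_ngrams : 0);
  std::vector<double> W((size_t)n_in * dim), C((size_t)vocab_size * dim, 0.0);
  for (auto& v : W) v = (rng.unif() - 0.5) / dim;

  std::vector<double> vin(dim), grad(dim);
  long long total_pairs = (long long)epochs * std::max(1LL, total_tokens);
  long long processed = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (auto& sent : S) {
      int n = sent.size();
      for (int i = 0; i < n; ++i) {
        double lr = alpha * (1.0 - (double)processed / (total_pairs + 1));
        if (lr < alpha * 1e-4) lr = alpha * 1e-4;
        ++processed;
        int b = 1 + rng.below(window);
        int w = sent[i];
        // compose input representation
        double denom = 1.0;
        double* Ww = &W[(size_t)w * dim];
        for (int d = 0; d < dim; ++d) vin[d] = Ww[d];
        if (use_sub) {
          for (int g : sub[w]) {
            double* Wg = &W[(size_t)(vocab_size + g) * dim];
            for (int d = 0; d < dim; ++d) vin[d] += Wg[d];
          }
          denom += sub[w].size();
          for (int d = 0; d < dim; ++d) vin[d] /= denom;
        }
        for (int j = i - b; j <= i + b; ++j) {
          if (j < 0 || j >= n || j == i) continue;
          int target = sent[j];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int k = 0; k <= negative; ++k) {
            int label, out;
            if (k == 0) { out = target; label = 1; }
            else {
              out = neg_table[rng.below(100000)];
              if (out == target) continue;
              label = 0;
            }
            double* Co = &C[(size_t)out * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += vin[d] * Co[d];
            double g = (label - sigmoid(dot)) * lr;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * Co[d];
              Co[d] += g * vin[d];
            }
          }
          if (use_sub) {
            double scale = 1.0 / denom;
            for (int d = 0; d < dim; ++d) Ww[d] += grad[d] * scale;
            for (int g : sub[w]) {
              double* Wg = &W[(size_t)(vocab_size + g) * dim];
              for (int d = 0; d < dim; ++d) Wg[d] += grad[d] * scale;
            }
            for (int d = 0; d < dim; ++d) vin[d] = Ww[d];
            if (!sub[w].empty()) {
              for (int g : sub[w]) {
                double* Wg = &W[(size_t)(vocab_size + g) * dim];
                for (int d = 0; d < dim; ++d) vin[d] += Wg[d];
              }
            }
            for (int d = 0; d < dim; ++d) vin[d] /= denom;
          } else {
            for (int d = 0; d < dim; ++d) { Ww[d] += grad[d]; vin[d] = Ww[d]; }
          }
        }
      }
    }
  }

  NumericMatrix word(vocab_size, dim);
  for (int w = 0; w < vocab_size; ++w) {
    if (use_sub) {
      double denom = 1.0 + sub[w].size();
      for (int d = 0; d < dim; ++d) {
        double v = W[(size_t)w * dim + d];
        for (int g : sub[w]) v += W[(size_t)(vocab_size + g) * dim + d];
        word(w, d) = v / denom;
      }
    } else {
      for (int d = 0; d < dim; ++d) word(w, d) = W[(size_t)w * dim + d];
    }
  }
  List out = List::create(_["word"] = word);
  if (use_sub) {
    NumericMatrix ng(n_ngrams, dim);
    for (int g = 0; g < n_ngrams; ++g)
      for (int d = 0; d < dim; ++d)
        ng(g, d) = W[(size_t)(vocab_size + g) * dim + d];
    out["ngram"] = ng;
  }
  return out;
}

// PV-DBOW: the document vector predicts each token of its sentences via
// negative sampling. doc_of_sent is 0-based.
// [[Rcpp::export]]
List train_dbow_cpp(List sents, IntegerVector doc_of_sent, int n_docs,
                    int vocab_size, int dim, int epochs, int negative,
                    double alpha, int seed) {
  std::vector<std::vector<int>> S = as_sentences(sents);
  XorShift rng(static_cast<uint64_t>(seed) * 2654435761ULL + 7ULL);
  std::vector<double> counts(vocab_size, 0.0);
  long long total_tokens = 0;
  for (auto& s : S) { total_tokens += s.size(); for (int w : s) counts[w] += 1.0; }
  std::vector<int> neg_table = build_neg_table(counts, 100000);

  std::vector<double> D((size_t)n_docs * dim), C((size_t)vocab_size * dim, 0.0);
  for (auto& v : D) v = (rng.unif() - 0.5) / dim;

  long long total_pairs = (long long)epochs * std::max(1LL, total_tokens);
  long long processed = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (size_t si = 0; si < S.size(); ++si) {
      double* Dd = &D[(size_t)doc_of_sent[si] * dim];
      for (int w : S[si]) {
        double lr = alpha * (1.0 - (double)processed / (total_pairs + 1));
        if (lr < alpha * 1e-4) lr = alpha * 1e-4;
        ++processed;
        for (int k = 0; k <= negative; ++k) {
          int label, out;
          if (k == 0) { out = w; label = 1; }
          else {
            out = neg_table[rng.below(100000)];
            if (out == w) continue;
            label = 0;
          }
          double* Co = &C[(size_t)out * dim];
          double dot = 0.0;
          for (int d = 0; d < dim; ++d) dot += Dd[d] * Co[d];
          double g = (label - sigmoid(dot)) * lr;
          for (int d = 0; d < dim; ++d) {
            double dd = Dd[d];
            Dd[d] += g * Co[d];
            Co[d] += g * dd;
          }
        }
      }
    }
  }
  NumericMatrix doc(n_docs, dim), word(vocab_size, dim);
  for (int i = 0; i < n_docs; ++i)
    for (int d = 0; d < dim; ++d) doc(i, d) = D[(size_t)i * dim + d];
  for (int w = 0; w < vocab_size; ++w)
    for (int d = 0; d < dim; ++d) word(w, d) = C[(size_t)w * dim + d];
  return List::create(_["doc"] = doc, _["word"] = word);
}

// Symmetric windowed co-occurrence counts with 1/distance weighting.
// [[Rcpp::export]]
List cooc_counts_cpp(List sents, int vocab_size, int window) {
  std::vector<std::vector<int>> S = as_sentences(sents);
  std::map<int64_t, double> acc;
  for (auto& s : S) {
    int n = s.size();
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j <= i + window && j < n; ++j) {
        double w = 1.0 / (j - i);
        acc[(int64_t)s[i] * vocab_size + s[j]] += w;
        acc[(int64_t)s[j] * vocab_size + s[i]] += w;
      }
  }
  int m = acc.size();
  IntegerVector ii(m), jj(m);
  NumericVector xx(m);
  int k = 0;
  for (auto& kv : acc) {
    ii[k] = kv.first / vocab_size;
    jj[k] = kv.first % vocab_size;
    xx[k] = kv.second;
    ++k;
  }
  return List::create(_["i"] = ii, _["j"] = jj, _["x"] = xx);
}

// AdaGrad factorization of the weighted log co-occurrence objective;
// returns main + context vectors summed.
// [[Rcpp::export]]
NumericMatrix train_glove_cpp(IntegerVector ii, IntegerVector jj,
                              NumericVector xx, int vocab_size, int dim,
                              int epochs, double x_max, double alpha_pow,
                              double eta, int seed) {
  int m = ii.size();
  XorShift rng(static_cast<uint64_t>(seed) * 2654435761ULL + 13ULL);
  std::vector<double> W((size_t)vocab_size * dim),
      Wt((size_t)vocab_size * dim), b(vocab_size, 0.0), bt(vocab_size, 0.0);
  for (auto& v : W) v = (rng.unif() - 0.5) / dim;
  for (auto& v : Wt) v = (rng.unif() - 0.5) / dim;
  std::vector<double> gW((size_t)vocab_size * dim, 1.0),
      gWt((size_t)vocab_size * dim, 1.0), gb(vocab_size, 1.0),
      gbt(vocab_size, 1.0);
  std::vector<int> order(m);
  for (int k = 0; k < m; ++k) order[k] = k;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int k = m - 1; k > 0; --k)
      std::swap(order[k], order[rng.below(k + 1)]);
    for (int k = 0; k < m; ++k) {
      int t = order[k];
      int i = ii[t], j = jj[t];
      double x = xx[t];
      double f = x > x_max ? 1.0 : std::pow(x / x_max, alpha_pow);
      double* wi = &W[(size_t)i * dim];
      double* wj = &Wt[(size_t)j * dim];
      double dot = b[i] + bt[j] - std::log(x);
      for (int d = 0; d < dim; ++d) dot += wi[d] * wj[d];
      double g = f * dot;
      if (g > 100.0) g = 100.0;
      if (g < -100.0) g = -100.0;
      for (int d = 0; d < dim; ++d) {
        double gi = g * wj[d], gj = g * wi[d];
        double* si = &gW[(size_t)i * dim + d];
        double* sj = &gWt[(size_t)j * dim + d];
        wi[d] -= eta * gi / std::sqrt(*si);
        wj[d] -= eta * gj / std::sqrt(*sj);
        *si += gi * gi;
        *sj += gj * gj;
      }
      b[i] -= eta * g / std::sqrt(gb[i]);
      bt[j] -= eta * g / std::sqrt(gbt[j]);
      gb[i] += g * g;
      gbt[j] += g * g;
    }
  }
  NumericMatrix out(vocab_size, dim);
  for (int w = 0; w < vocab_size; ++w)
    for (int d = 0; d < dim; ++d)
      out(w, d) = W[(size_t)w * dim + d] + Wt[(size_t)w * dim + d];
  return out;
}
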