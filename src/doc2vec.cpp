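// Distributed-memory document embedding trainer.
//
// One vector per document and one per vocabulary token. At each position t
// the hidden state is the mean of the document vector and the vectors of the
// preceding `window` tokens; a dense softmax over the vocabulary (with bias)
// predicts token t. Plain SGD with linearly decaying learning rate,
// single-threaded, deterministic under the given seed. Vocabularies here are
// small (<= 125 distinct k-mers for k = 3 over A,C,G,U,N), so the full
// softmax is affordable and no sampling approximation is used.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export(name = ".dm_train_cpp")]]
List dm_train_cpp(List docs, int vocab_size, int dim, int window,
                  int epochs, double lr, int seed) {
  const int n_docs = docs.size();
  if (dim < 2) stop("embedding dimension must be >= 2");
  if (window < 1) stop("context window must be >= 1");

  std::vector<std::vector<int>> D(n_docs);
  long long total_pos = 0;
  for (int d = 0; d < n_docs; ++d) {
    IntegerVector v = docs[d];
    D[d].assign(v.begin(), v.end());
    total_pos += v.size();
  }
  if (total_pos == 0) stop("corpus has no tokens");

  std::mt19937_64 rng(static_cast<unsigned long long>(seed));
  std::uniform_real_distribution<double> unif(-0.5 / dim, 0.5 / dim);

  // doc vectors, input token vectors, output (softmax) matrix + bias
  std::vector<double> docv((size_t)n_docs * dim);
  std::vector<double> tokv((size_t)vocab_size * dim);
  std::vector<double> out((size_t)vocab_size * dim, 0.0);
  std::vector<double> bias(vocab_size, 0.0);
  for (auto &x : docv) x = unif(rng);
  for (auto &x : tokv) x = unif(rng);

  std::vector<double> hidden(dim), grad_h(dim), logits(vocab_size);

  const double lr_min = lr * 1e-4;
  const double total_updates = (double)total_pos * epochs;
  long long done = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int d = 0; d < n_docs; ++d) {
      const std::vector<int> &doc = D[d];
      const int len = (int)doc.size();
      double *dv = &docv[(size_t)d * dim];
      for (int t = 0; t < len; ++t) {
        double alpha = lr - (lr - lr_min) * ((double)done / total_updates);
        ++done;
        const int c0 = t - window < 0 ? 0 : t - window;
        const int n_ctx = t - c0;           // context tokens actually present
        const double denom = 1.0 + n_ctx;   // doc vector always participates

        for (int k = 0; k < dim; ++k) hidden[k] = dv[k];
        for (int c = c0; c < t; ++c) {
          const double *wv = &tokv[(size_t)doc[c] * dim];
          for (int k = 0; k < dim; ++k) hidden[k] += wv[k];
        }
        for (int k = 0; k < dim; ++k) hidden[k] /= denom;

        // softmax over the vocabulary
        double mx = -1e300;
        for (int w = 0; w < vocab_size; ++w) {
          const double *ow = &out[(size_t)w * dim];
          double z = bias[w];
          for (int k = 0; k < dim; ++k) z += ow[k] * hidden[k];
          logits[w] = z;
          if (z > mx) mx = z;
        }
        double zsum = 0.0;
        for (int w = 0; w < vocab_size; ++w) {
          logits[w] = std::exp(logits[w] - mx);
          zsum += logits[w];
        }

        const int target = doc[t];
        std::fill(grad_h.begin(), grad_h.end(), 0.0);
        for (int w = 0; w < vocab_size; ++w) {
          const double p = logits[w] / zsum;
          const double g = p - (w == target ? 1.0 : 0.0);  // dL/dz_w
          double *ow = &out[(size_t)w * dim];
          for (int k = 0; k < dim; ++k) {
            grad_h[k] += g * ow[k];
            ow[k] -= alpha * g * hidden[k];
          }
          bias[w] -= alpha * g;
        }

        // distribute the hidden gradient over doc + context vectors (mean)
        for (int k = 0; k < dim; ++k) grad_h[k] *= alpha / denom;
        for (int k = 0; k < dim; ++k) dv[k] -= grad_h[k];
        for (int c = c0; c < t; ++c) {
          double *wv = &tokv[(size_t)doc[c] * dim];
          for (int k = 0; k < dim; ++k) wv[k] -= grad_h[k];
        }
      }
    }
  }

  NumericMatrix doc_mat(n_docs, dim), tok_mat(vocab_size, dim);
  for (int d = 0; d < n_docs; ++d)
    for (int k = 0; k < dim; ++k) doc_mat(d, k) = docv[(size_t)d * dim + k];
  for (int w = 0; w < vocab_size; ++w)
    for (int k = 0; k < dim; ++k) tok_mat(w, k) = tokv[(size_t)w * dim + k];
  return List::create(_["doc"] = doc_mat, _["token"] = tok_mat);
}
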