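#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Skip-gram with negative sampling over random-walk corpora, trained by
// single-threaded SGD so that results are reproducible under R's RNG.
// Walks are encoded as 1-based node indices; the context window shrinks
// uniformly at random per centre word, as in word2vec.
//
// Returns the input (centre) embedding matrix, n_nodes x dim.
// [[Rcpp::export]]
NumericMatrix skipgram_train_cpp(List walks, int n_nodes, int dim,
                                 int window, int negative, int epochs,
                                 double alpha0) {
  RNGScope scope;  // ties into R's set.seed

  // node-major contiguous storage (row i of the returned matrix lives at
  // offset i*dim), so the inner dot-product loops stream through memory
  std::vector<double> syn0((size_t)n_nodes * dim);  // centre vectors
  std::vector<double> syn1((size_t)n_nodes * dim, 0.0);  // context vectors

  for (int i = 0; i < n_nodes; ++i)
    for (int d = 0; d < dim; ++d)
      syn0[(size_t)i * dim + d] = (unif_rand() - 0.5) / dim;

  // unigram^0.75 negative-sampling table
  std::vector<double> counts(n_nodes, 0.0);
  long long total_tokens = 0;
  for (int w = 0; w < walks.size(); ++w) {
    IntegerVector walk = walks[w];
    total_tokens += walk.size();
    for (int t = 0; t < walk.size(); ++t) counts[walk[t] - 1] += 1.0;
  }
  const int table_size = 100000;
  std::vector<int> neg_table(table_size);
  double z = 0.0;
  for (int i = 0; i < n_nodes; ++i) z += std::pow(counts[i], 0.75);
  {
    int i = 0;
    double cum = std::pow(counts[0], 0.75) / z;
    for (int t = 0; t < table_size; ++t) {
      neg_table[t] = i;
      if ((double)(t + 1) / table_size > cum && i < n_nodes - 1) {
        ++i;
        cum += std::pow(counts[i], 0.75) / z;
      }
    }
  }

  std::vector<double> grad(dim);
  long long processed = 0;
  const long long budget = (long long)epochs * total_tokens;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int w = 0; w < walks.size(); ++w) {
      IntegerVector walk = walks[w];
      int len = walk.size();
      for (int t = 0; t < len; ++t) {
        double alpha = alpha0 * (1.0 - (double)processed / (budget + 1));
        if (alpha < alpha0 * 1e-4) alpha = alpha0 * 1e-4;
        ++processed;
        int centre = walk[t] - 1;
        int b = (int)(unif_rand() * window);  // shrink window
        for (int off = b - window; off <= window - b; ++off) {
          if (off == 0) continue;
          int tc = t + off;
          if (tc < 0 || tc >= len) continue;
          int ctx = walk[tc] - 1;
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int nsi = 0; nsi <= negative; ++nsi) {
            int target;
            double label;
            if (nsi == 0) {
              target = ctx;
              label = 1.0;
            } else {
              target = neg_table[(int)(unif_rand() * table_size)];
              if (target == ctx) continue;
              label = 0.0;
            }
            double* v0 = &syn0[(size_t)centre * dim];
            double* v1 = &syn1[(size_t)target * dim];
            double f = 0.0;
            for (int d = 0; d < dim; ++d) f += v0[d] * v1[d];
            double sig = 1.0 / (1.0 + std::exp(-f));
            double g = (label - sig) * alpha;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * v1[d];
              v1[d] += g * v0[d];
            }
          }
          double* v0 = &syn0[(size_t)centre * dim];
          for (int d = 0; d < dim; ++d) v0[d] += grad[d];
        }
      }
    }
  }
  NumericMatrix out(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i)
    for (int d = 0; d < dim; ++d)
      out(i, d) = syn0[(size_t)i * dim + d];
  return out;
}
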