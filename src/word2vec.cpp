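// Skip-gram word2vec with hierarchical softmax.
//
// Vocabulary is built on the R side and passed as 0-based token ids with
// per-id counts sorted in decreasing frequency (the Huffman construction
// below requires that ordering).  All randomness (vector initialisation,
// per-position window shrinking) goes through R's RNG so a set.seed() on the
// R side makes training fully reproducible; the loop is single-threaded.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Classic two-queue Huffman construction over count-sorted vocabulary.
// Fills, per word, the list of inner-node indices on its root path ("point")
// and the binary branch codes ("code").
static void build_huffman(const std::vector<long long>& cnt_in,
                          std::vector<std::vector<int> >& point,
                          std::vector<std::vector<char> >& code) {
  const int V = (int)cnt_in.size();
  std::vector<long long> count(2 * V - 1);
  std::vector<int> parent(2 * V - 1), binary(2 * V - 1, 0);
  for (int i = 0; i < V; ++i) count[i] = cnt_in[i];
  long long big = 1;
  for (int i = 0; i < V; ++i) big += cnt_in[i];
  for (int i = V; i < 2 * V - 1; ++i) count[i] = big;  // sentinel: larger than any sum

  int pos1 = V - 1, pos2 = V;
  for (int a = 0; a < V - 1; ++a) {
    int m1, m2;
    if (pos1 >= 0 && count[pos1] < count[pos2]) m1 = pos1--; else m1 = pos2++;
    if (pos1 >= 0 && count[pos1] < count[pos2]) m2 = pos1--; else m2 = pos2++;
    count[V + a] = count[m1] + count[m2];
    parent[m1] = V + a;
    parent[m2] = V + a;
    binary[m2] = 1;
  }
  point.assign(V, std::vector<int>());
  code.assign(V, std::vector<char>());
  for (int a = 0; a < V; ++a) {
    std::vector<int> pt;
    std::vector<char> cd;
    int b = a;
    while (b != 2 * V - 2) {
      cd.push_back((char)binary[b]);
      pt.push_back(parent[b] - V);  // inner-node index in [0, V-2]
      b = parent[b];
    }
    // store root-first, as the update walks top-down
    point[a].assign(pt.rbegin(), pt.rend());
    code[a].assign(cd.rbegin(), cd.rend());
  }
}

// docs: list of integer vectors of 0-based vocab ids (already min_count
// filtered).  counts: per-id corpus frequency, decreasing in id.
// Returns a dim x V matrix (one column per vocabulary word).
// [[Rcpp::export]]
NumericMatrix cpp_sg_hs_train(List docs, NumericVector counts, int dim,
                              int window, int epochs, double alpha0,
                              double min_alpha) {
  const int V = counts.size();
  if (V < 1) stop("empty vocabulary");
  std::vector<long long> cnt(V);
  long long total_tokens = 0;
  for (int i = 0; i < V; ++i) {
    cnt[i] = (long long)counts[i];
    total_tokens += cnt[i];
  }
  if (V >= 2) {
    for (int i = 1; i < V; ++i)
      if (cnt[i] > cnt[i - 1]) stop("vocabulary counts must be non-increasing");
  }

  std::vector<std::vector<int> > point;
  std::vector<std::vector<char> > code;
  if (V > 1) build_huffman(cnt, point, code);

  NumericMatrix syn0(dim, V);
  for (int j = 0; j < V; ++j)
    for (int d = 0; d < dim; ++d)
      syn0(d, j) = (unif_rand() - 0.5) / dim;
  std::vector<double> syn1((std::size_t)dim * std::max(V - 1, 1), 0.0);
  std::vector<double> neu1e(dim);

  const double span = (double)epochs * (double)total_tokens + 1.0;
  long long processed = 0;
  const int nd = docs.size();

  for (int ep = 0; ep < epochs; ++ep) {
    for (int di = 0; di < nd; ++di) {
      IntegerVector doc = docs[di];
      const int L = doc.size();
      for (int pos = 0; pos < L; ++pos) {
        const int w = doc[pos];          // center word: its Huffman path is trained
        double alpha = alpha0 * (1.0 - (double)processed / span);
        if (alpha < min_alpha) alpha = min_alpha;
        ++processed;
        if (V < 2) continue;
        const int red = 1 + (int)(unif_rand() * window);  // half-window in 1..window
        for (int off = -red; off <= red; ++off) {
          if (off == 0) continue;
          const int cpos = pos + off;
          if (cpos < 0 || cpos >= L) continue;
          const int c = doc[cpos];       // context word: its input vector is updated
          double* v0 = &syn0(0, c);
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          const std::vector<int>& pt = point[w];
          const std::vector<char>& cd = code[w];
          for (std::size_t d = 0; d < pt.size(); ++d) {
            double* v1 = &syn1[(std::size_t)dim * pt[d]];
            double f = 0.0;
            for (int k = 0; k < dim; ++k) f += v0[k] * v1[k];
            const double g = (1.0 - (double)cd[d] - sigmoid(f)) * alpha;
            for (int k = 0; k < dim; ++k) neu1e[k] += g * v1[k];
            for (int k = 0; k < dim; ++k) v1[k] += g * v0[k];
          }
          for (int k = 0; k < dim; ++k) v0[k] += neu1e[k];
        }
      }
    }
  }
  return syn0;
}
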