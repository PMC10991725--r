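#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA.
//
// doc_id / word_id: 0-based token-instance vectors (one entry per token
// occurrence). Uses R's RNG so results are reproducible under set.seed().
// When check_counts is true the topic-word bookkeeping is re-verified
// against the corpus counts after every sweep and any drift aborts.
// [[Rcpp::export(name = ".lda_gibbs_cpp")]]
List lda_gibbs_cpp(IntegerVector doc_id, IntegerVector word_id,
                   int n_docs, int n_words, int n_topics,
                   double alpha, double beta, int n_iter,
                   bool check_counts = false) {
  const int n_tok = doc_id.size();
  IntegerVector z(n_tok);
  IntegerMatrix ndk(n_docs, n_topics);
  IntegerMatrix nkw(n_topics, n_words);
  IntegerVector nk(n_topics);
  std::vector<double> prob(n_topics);

  // reference corpus counts for the conservation check
  std::vector<int> word_count;
  if (check_counts) {
    word_count.assign(n_words, 0);
    for (int i = 0; i < n_tok; ++i) word_count[word_id[i]]++;
  }

  // random initial topic per token
  for (int i = 0; i < n_tok; ++i) {
    int k = (int)(unif_rand() * n_topics);
    if (k >= n_topics) k = n_topics - 1;
    z[i] = k;
    ndk(doc_id[i], k)++;
    nkw(k, word_id[i])++;
    nk[k]++;
  }

  const double Fbeta = n_words * beta;
  for (int iter = 0; iter < n_iter; ++iter) {
    for (int i = 0; i < n_tok; ++i) {
      const int d = doc_id[i], w = word_id[i], old = z[i];
      ndk(d, old)--; nkw(old, w)--; nk[old]--;
      double total = 0.0;
      for (int k = 0; k < n_topics; ++k) {
        total += (ndk(d, k) + alpha) * (nkw(k, w) + beta) / (nk[k] + Fbeta);
        prob[k] = total;
      }
      double u = unif_rand() * total;
      int knew = 0;
      while (knew < n_topics - 1 && prob[knew] < u) ++knew;
      z[i] = knew;
      ndk(d, knew)++; nkw(knew, w)++; nk[knew]++;
    }
    if (check_counts) {
      for (int w = 0; w < n_words; ++w) {
        int s = 0;
        for (int k = 0; k < n_topics; ++k) s += nkw(k, w);
        if (s != word_count[w])
          stop("Gibbs count conservation violated at iteration %d, word %d",
               iter + 1, w + 1);
      }
    }
  }

  return List::create(_["z"] = z, _["ndk"] = ndk, _["nkw"] = nkw,
                      _["nk"] = nk);
}
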