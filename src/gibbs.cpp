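#include <Rcpp.h>
using namespace Rcpp;

// One full collapsed-Gibbs sweep over all token-level topic assignments.
//
// For token i of document d the full conditional is
//   p(z_di = k | .) ~ (n_dk^{-di} + alpha)
//                    * (n_kv^{-di} + beta) / (n_k^{-di} + V beta)
//                    * exp(-0.5 * (y*_d - eta' zbar_d^{(k)} - gamma' x_d)^2)
// where zbar_d^{(k)} is the empirical topic-frequency vector of document d
// with token i assigned to k.  The response factor is dropped when
// supervised = false.  Probabilities are floored at 1e-300 before
// normalization.  All randomness comes from R's RNG (unif_rand), so runs
// are reproducible under set.seed().
//
// Count matrices are updated in place; the caller owns them exclusively.
// [[Rcpp::export]]
void cpp_z_sweep(IntegerVector z, IntegerVector doc_of, IntegerVector word_of,
                 IntegerMatrix n_dk, IntegerMatrix n_kv, IntegerVector n_k,
                 IntegerVector doc_len, double alpha, double beta,
                 NumericVector y_star, NumericVector eta, NumericVector gx,
                 bool supervised) {
  const int T = z.size();
  const int K = n_dk.ncol();
  const int V = n_kv.ncol();
  const int D = n_dk.nrow();
  std::vector<double> p(K);
  // running eta' n_dk row per document (only used when supervised)
  std::vector<double> s(D, 0.0);
  if (supervised) {
    for (int d = 0; d < D; ++d) {
      double acc = 0.0;
      for (int k = 0; k < K; ++k) acc += eta[k] * n_dk(d, k);
      s[d] = acc;
    }
  }
  for (int t = 0; t < T; ++t) {
    const int d = doc_of[t];
    const int w = word_of[t];
    const int old = z[t];
    n_dk(d, old)--; n_kv(old, w)--; n_k[old]--;
    if (supervised) s[d] -= eta[old];
    double total = 0.0;
    for (int k = 0; k < K; ++k) {
      double pk = (n_dk(d, k) + alpha) *
                  (n_kv(k, w) + beta) / (n_k[k] + V * beta);
      if (supervised) {
        const double m = (s[d] + eta[k]) / doc_len[d] + gx[d];
        const double r = y_star[d] - m;
        pk *= std::exp(-0.5 * r * r);
      }
      if (pk < 1e-300) pk = 1e-300;
      p[k] = pk;
      total += pk;
    }
    double u = unif_rand() * total;
    int knew = 0;
    double cum = p[0];
    while (u > cum && knew < K - 1) cum += p[++knew];
    z[t] = knew;
    n_dk(d, knew)++; n_kv(knew, w)++; n_k[knew]++;
    if (supervised) s[d] += eta[knew];
  }
}
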