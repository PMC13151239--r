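#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Skip-gram with negative sampling over a fixed (centre, context) pair
// corpus. Sequential SGD in corpus order, re-shuffled every iteration with R's
// RNG, linearly decaying learning rate — the classic word2vec scheme.
// Deterministic under set.seed() in the calling R session.
// [[Rcpp::export]]
NumericMatrix sgns_train_cpp(IntegerVector centres, IntegerVector contexts,
                             int n, int dim, int n_neg, int iters,
                             double alpha, NumericVector neg_cdf,
                             NumericMatrix w_in_init) {
  const R_xlen_t npairs = centres.size();
  std::vector<double> win(n * (size_t)dim), wout(n * (size_t)dim, 0.0);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < dim; ++d)
      win[(size_t)i * dim + d] = w_in_init(i, d);

  std::vector<R_xlen_t> ord(npairs);
  for (R_xlen_t i = 0; i < npairs; ++i) ord[i] = i;
  const double *cdf = neg_cdf.begin();
  const int ncdf = neg_cdf.size();
  std::vector<double> e(dim);
  const double total = (double)iters * npairs;
  double done = 0.0;

  for (int it = 0; it < iters; ++it) {
    // Fisher-Yates with R's RNG for reproducibility
    for (R_xlen_t i = npairs - 1; i > 0; --i) {
      R_xlen_t j = (R_xlen_t)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(ord[i], ord[j]);
    }
    for (R_xlen_t s = 0; s < npairs; ++s, done += 1.0) {
      double lr = alpha * (1.0 - done / total);
      if (lr < alpha * 1e-4) lr = alpha * 1e-4;
      const int c = centres[ord[s]] - 1;
      const int o = contexts[ord[s]] - 1;
      double *xc = &win[(size_t)c * dim];
      std::fill(e.begin(), e.end(), 0.0);
      for (int k = 0; k <= n_neg; ++k) {
        int t;
        double label;
        if (k == 0) { t = o; label = 1.0; }
        else {
          double u = unif_rand();
          t = (int)(std::upper_bound(cdf, cdf + ncdf, u) - cdf);
          if (t >= ncdf) t = ncdf - 1;
          if (t == o) continue;
          label = 0.0;
        }
        double *yt = &wout[(size_t)t * dim];
        double f = 0.0;
        for (int d = 0; d < dim; ++d) f += xc[d] * yt[d];
        double g = (1.0 / (1.0 + std::exp(-f)) - label) * lr;
        for (int d = 0; d < dim; ++d) {
          e[d] += g * yt[d];
          yt[d] -= g * xc[d];
        }
      }
      for (int d = 0; d < dim; ++d) xc[d] -= e[d];
    }
  }
  NumericMatrix out(n, dim);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < dim; ++d)
      out(i, d) = win[(size_t)i * dim + d];
  return out;
}
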