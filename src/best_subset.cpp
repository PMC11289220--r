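// Exact best-subset search over precomputed weighted cross-products.
//
// G = [1 X]' W [1 X], g = [1 X]' W y, yty = y' W y.  For a candidate term
// subset S the weighted RSS is yty - b_S' beta_S with beta_S solving the
// normal equations restricted to {intercept} + S, so each subset costs one
// small symmetric solve and no pass over the data.  All subsets of each
// requested size are enumerated; the minimiser is exact, matching what an
// exhaustive per-subset least-squares enumeration would return.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List best_subset_search(const arma::mat& G, const arma::vec& g,
                        double yty, const IntegerVector& sizes) {
  const int p = static_cast<int>(G.n_rows) - 1;
  List out(sizes.size());
  for (int si = 0; si < sizes.size(); ++si) {
    const int s = sizes[si];
    if (s < 1 || s > p) stop("subset size out of range");
    std::vector<int> comb(s);
    for (int i = 0; i < s; ++i) comb[i] = i;
    double best_rss = R_PosInf;
    std::vector<int> best_comb;
    arma::vec best_beta;
    bool any_ok = false, skipped = false;
    arma::mat A(s + 1, s + 1);
    arma::vec b(s + 1), beta;
    for (;;) {
      A(0, 0) = G(0, 0);
      b(0) = g(0);
      for (int i = 0; i < s; ++i) {
        const int ci = comb[i] + 1;
        A(0, i + 1) = G(0, ci);
        A(i + 1, 0) = G(ci, 0);
        b(i + 1) = g(ci);
        for (int j = 0; j <= i; ++j) {
          const int cj = comb[j] + 1;
          A(i + 1, j + 1) = G(ci, cj);
          A(j + 1, i + 1) = G(cj, ci);
        }
      }
      const bool ok = arma::solve(beta, A, b,
                                  arma::solve_opts::likely_sympd +
                                  arma::solve_opts::no_approx);
      if (ok) {
        double rss = yty - arma::dot(beta, b);
        if (rss < 0) rss = 0;
        if (rss < best_rss) {
          best_rss = rss;
          best_comb = comb;
          best_beta = beta;
        }
        any_ok = true;
      } else {
        skipped = true;
      }
      int i = s - 1;
      while (i >= 0 && comb[i] == p - s + i) --i;
      if (i < 0) break;
      ++comb[i];
      for (int j = i + 1; j < s; ++j) comb[j] = comb[j - 1] + 1;
    }
    IntegerVector idx(best_comb.size());
    for (size_t i = 0; i < best_comb.size(); ++i) idx[i] = best_comb[i] + 1;
    out[si] = List::create(_["size"] = s, _["ok"] = any_ok,
                           _["skipped"] = skipped, _["indices"] = idx,
                           _["rss"] = best_rss,
                           _["beta"] = NumericVector(best_beta.begin(),
                                                     best_beta.end()));
  }
  return out;
}
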