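#include <Rcpp.h>
using namespace Rcpp;

// All kernels assume the pedigree is supplied in topological order:
// for animal i (0-based), sire[i] and dam[i] are 1-based positions < i + 1,
// or 0 when the parent is unknown.

// Kinship matrix by the tabular method. K(i,i) = 0.5 * (1 + F_i) with
// F_i = K(sire_i, dam_i); off-diagonals K(i,j) = 0.5 * (K(j,s) + K(j,d)).
// Dense: memory is O(n^2), intended for desk-scale pedigrees.
// [[Rcpp::export]]
NumericMatrix kinship_dense_cpp(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericMatrix K(n, n);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i], d = dam[i];
    const double fsd = (s > 0 && d > 0) ? K(s - 1, d - 1) : 0.0;
    K(i, i) = 0.5 * (1.0 + fsd);
    for (int j = 0; j < i; ++j) {
      const double ks = (s > 0) ? K(j, s - 1) : 0.0;
      const double kd = (d > 0) ? K(j, d - 1) : 0.0;
      const double v = 0.5 * (ks + kd);
      K(i, j) = v;
      K(j, i) = v;
    }
  }
  return K;
}

// Expected genetic contribution of each source animal to every animal:
// c(k -> j) = 1 if j == k, else 0.5 * c(k -> sire_j) + 0.5 * c(k -> dam_j),
// contribution through an unknown parent is 0. Rows index sources.
// [[Rcpp::export]]
NumericMatrix contrib_forward_cpp(IntegerVector sire, IntegerVector dam,
                                  IntegerVector sources) {
  const int n = sire.size(), m = sources.size();
  NumericMatrix M(m, n);
  std::vector<int> src_at(n, -1);
  for (int k = 0; k < m; ++k) src_at[sources[k] - 1] = k;
  for (int i = 0; i < n; ++i) {
    const int s = sire[i], d = dam[i];
    if (s > 0)
      for (int k = 0; k < m; ++k) M(k, i) += 0.5 * M(k, s - 1);
    if (d > 0)
      for (int k = 0; k < m; ++k) M(k, i) += 0.5 * M(k, d - 1);
    // the recursion terminates at the source itself: c(k -> k) = 1
    if (src_at[i] >= 0) M(src_at[i], i) = 1.0;
  }
  return M;
}

// Dual (upward) accumulation: given weights w over animals (e.g. 1/n on the
// members of a reference cohort), returns for every animal k the weighted sum
// of path contributions q_k = sum_j w_j * c(k -> j).
// [[Rcpp::export]]
NumericVector contrib_backward_cpp(IntegerVector sire, IntegerVector dam,
                                   NumericVector w) {
  const int n = sire.size();
  NumericVector g = clone(w);
  for (int i = n - 1; i >= 0; --i) {
    const double gi = g[i];
    if (gi == 0.0) continue;
    if (sire[i] > 0) g[sire[i] - 1] += 0.5 * gi;
    if (dam[i] > 0) g[dam[i] - 1] += 0.5 * gi;
  }
  return g;
}
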