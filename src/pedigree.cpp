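#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Tabular-method additive relationship matrix.
// sire/dam are 1-based positions into the (topologically sorted) pedigree,
// 0 = unknown. a_ij = (a_sj + a_dj)/2 for j < i, a_ii = 1 + a_sd/2.
// [[Rcpp::export]]
arma::mat tabular_a_matrix(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  arma::mat A(n, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i] - 1, d = dam[i] - 1;
    for (int j = 0; j < i; ++j) {
      double v = 0.0;
      if (s >= 0) v += 0.5 * A(s, j);
      if (d >= 0) v += 0.5 * A(d, j);
      A(i, j) = A(j, i) = v;
    }
    double aii = 1.0;
    if (s >= 0 && d >= 0) aii += 0.5 * A(s, d);
    A(i, i) = aii;
  }
  return A;
}

// Meuwissen & Luo (1992) inbreeding coefficients for a sorted pedigree.
// Mendelian variance d_j uses F = -1 for unknown parents so that the
// one-known / none-known cases give 0.75 and 1.
// [[Rcpp::export]]
NumericVector meuwissen_luo_f(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericVector F(n);
  std::vector<double> D(n), L(n, 0.0);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i] - 1, d = dam[i] - 1;
    const double fs = s >= 0 ? F[s] : -1.0;
    const double fd = d >= 0 ? F[d] : -1.0;
    D[i] = 0.5 - 0.25 * (fs + fd);
    if (s < 0 || d < 0) {
      F[i] = 0.0;
      continue;
    }
    // accumulate a_ii = sum_j L_j^2 d_j walking ancestors youngest-first
    std::fill(L.begin(), L.begin() + i + 1, 0.0);
    L[i] = 1.0;
    double aii = 0.0;
    for (int j = i; j >= 0; --j) {
      if (L[j] == 0.0) continue;
      const int js = sire[j] - 1, jd = dam[j] - 1;
      if (js >= 0) L[js] += 0.5 * L[j];
      if (jd >= 0) L[jd] += 0.5 * L[j];
      aii += L[j] * L[j] * D[j];
    }
    F[i] = aii - 1.0;
  }
  return F;
}
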