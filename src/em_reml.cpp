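#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// EM-REML on Henderson's mixed-model equations for
//   y = X b + Z_p p + Z_a a_D (+ S a_S) + e.
// The coefficient matrix is assembled dense in the 1/sig2_e scaling, so its
// inverse directly provides the prediction-error (co)variances that the EM
// trace terms need:
//   sig2_pen <- (p'p + tr C^pp) / n_pens
//   G_kl     <- (u_k' Ainv u_l + tr(Ainv C^kl)) / q
//   sig2_e   <- y'(y - W s) / (n - rank X)
// Iterates until the largest relative parameter change drops below tol.
// [[Rcpp::export]]
List em_reml_cpp(const arma::vec& y, const arma::mat& X,
                 const IntegerVector& pen, const IntegerVector& animal,
                 const IntegerVector& srow_ptr, const IntegerVector& srow_col,
                 const NumericVector& srow_val,
                 const IntegerVector& Ap, const IntegerVector& Ai,
                 const NumericVector& Ax,
                 int n_pens, int q,
                 bool social, bool use_pen, bool use_genetic,
                 const List& start, double tol, int maxit) {
  const int n = y.n_elem, p = X.n_cols;

  // no random effects: REML reduces to the df-corrected OLS residual variance
  if (!use_pen && !use_genetic) {
    arma::vec bhat = arma::solve(X, y);
    arma::vec r = y - X * bhat;
    return List::create(_["sigma2_e"] = arma::dot(r, r) / (n - p),
                        _["b"] = bhat, _["converged"] = true,
                        _["iterations"] = 0);
  }

  const int off_pen = p;
  const int off_gD = p + (use_pen ? n_pens : 0);
  const int off_gS = off_gD + q;
  const int m = off_gD + (use_genetic ? (social ? 2 * q : q) : 0);

  // dense W = [X | Z_p | Z_a | S]
  arma::mat W(n, m, arma::fill::zeros);
  W.cols(0, p - 1) = X;
  if (use_pen)
    for (int i = 0; i < n; ++i) W(i, off_pen + pen[i]) = 1.0;
  if (use_genetic) {
    for (int i = 0; i < n; ++i) W(i, off_gD + animal[i]) = 1.0;
    if (social && srow_ptr.size() > 0)
      for (int i = 0; i < n; ++i)
        for (int k = srow_ptr[i]; k < srow_ptr[i + 1]; ++k)
          W(i, off_gS + srow_col[k]) = srow_val[k];
  }
  const arma::mat C0 = W.t() * W;
  const arma::vec Wy = W.t() * y;

  double s2e = as<double>(start["sigma2_e"]);
  double s2p = use_pen ? as<double>(start["sigma2_pen"]) : 0.0;
  double s2a = 0.0;
  arma::mat G(2, 2, arma::fill::eye);
  if (use_genetic) {
    if (social) G = as<arma::mat>(start["G"]);
    else s2a = as<double>(start["sigma2_a"]);
  }

  bool converged = false;
  int iter = 0;
  arma::vec s;
  for (iter = 1; iter <= maxit; ++iter) {
    arma::mat M = C0 / s2e;
    if (use_pen)
      for (int j = 0; j < n_pens; ++j) M(off_pen + j, off_pen + j) += 1.0 / s2p;
    if (use_genetic && social) {
      arma::mat Ginv = arma::inv_sympd(G);
      for (int a = 0; a < q; ++a)
        for (int k = Ap[a]; k < Ap[a + 1]; ++k) {
          const int l = Ai[k]; const double v = Ax[k];
          M(off_gD + l, off_gD + a) += Ginv(0, 0) * v;
          M(off_gD + l, off_gS + a) += Ginv(0, 1) * v;
          M(off_gS + l, off_gD + a) += Ginv(1, 0) * v;
          M(off_gS + l, off_gS + a) += Ginv(1, 1) * v;
        }
    } else if (use_genetic) {
      for (int a = 0; a < q; ++a)
        for (int k = Ap[a]; k < Ap[a + 1]; ++k)
          M(off_gD + Ai[k], off_gD + a) += Ax[k] / s2a;
    }
    arma::mat Cinv;
    if (!arma::inv_sympd(Cinv, M))
      stop("mixed-model equations are singular at EM iteration %d", iter);
    s = Cinv * (Wy / s2e);

    const double s2e_new = arma::dot(y, y - W * s) / (n - p);
    double s2p_new = s2p, s2a_new = s2a;
    arma::mat G_new = G;
    if (use_pen) {
      double ss = 0.0;
      for (int j = 0; j < n_pens; ++j)
        ss += s[off_pen + j] * s[off_pen + j] + Cinv(off_pen + j, off_pen + j);
      s2p_new = ss / n_pens;
    }
    if (use_genetic && social) {
      double qDD = 0.0, qSS = 0.0, qDS = 0.0;
      double tDD = 0.0, tSS = 0.0, tDS = 0.0;
      for (int a = 0; a < q; ++a)
        for (int k = Ap[a]; k < Ap[a + 1]; ++k) {
          const int l = Ai[k]; const double v = Ax[k];
          qDD += s[off_gD + a] * v * s[off_gD + l];
          qSS += s[off_gS + a] * v * s[off_gS + l];
          qDS += s[off_gD + a] * v * s[off_gS + l];
          tDD += v * Cinv(off_gD + l, off_gD + a);
          tSS += v * Cinv(off_gS + l, off_gS + a);
          tDS += v * Cinv(off_gS + l, off_gD + a);
        }
      G_new(0, 0) = (qDD + tDD) / q;
      G_new(1, 1) = (qSS + tSS) / q;
      G_new(0, 1) = G_new(1, 0) = (qDS + tDS) / q;
    } else if (use_genetic) {
      double qf = 0.0, tr = 0.0;
      for (int a = 0; a < q; ++a)
        for (int k = Ap[a]; k < Ap[a + 1]; ++k) {
          qf += s[off_gD + a] * Ax[k] * s[off_gD + Ai[k]];
          tr += Ax[k] * Cinv(off_gD + Ai[k], off_gD + a);
        }
      s2a_new = (qf + tr) / q;
    }

    double delta = std::abs(s2e_new - s2e) / std::max(std::abs(s2e), 1e-10);
    if (use_pen)
      delta = std::max(delta,
                       std::abs(s2p_new - s2p) / std::max(std::abs(s2p), 1e-10));
    if (use_genetic && social) {
      for (int a = 0; a < 2; ++a)
        for (int l = a; l < 2; ++l)
          delta = std::max(delta, std::abs(G_new(a, l) - G(a, l)) /
                                      std::max(std::abs(G(a, l)), 1e-10));
    } else if (use_genetic) {
      delta = std::max(delta,
                       std::abs(s2a_new - s2a) / std::max(std::abs(s2a), 1e-10));
    }
    s2e = s2e_new; s2p = s2p_new; s2a = s2a_new; G = G_new;
    if (delta < tol) { converged = true; break; }
  }

  List out = List::create(_["sigma2_e"] = s2e, _["converged"] = converged,
                          _["iterations"] = std::min(iter, maxit),
                          _["b"] = arma::vec(s.head(p)));
  if (use_pen) out["sigma2_pen"] = s2p;
  if (use_genetic) {
    if (social) {
      out["G"] = G;
      out["aD"] = arma::vec(s.subvec(off_gD, off_gD + q - 1));
      out["aS"] = arma::vec(s.subvec(off_gS, off_gS + q - 1));
    } else {
      out["sigma2_a"] = s2a;
      out["aD"] = arma::vec(s.subvec(off_gD, off_gD + q - 1));
    }
  }
  return out;
}
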