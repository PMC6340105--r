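#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Single-site Gibbs sampler for the social animal model
//   y = X b + Z_p p + Z_a a_D + S a_S + e
// with priors p ~ N(0, I sig2_pen), (a_D, a_S) ~ N(0, G (x) A) (effect-major
// stacking gives prior precision G^-1 (x) A^-1), e ~ N(0, I sig2_e), and
// bounded-flat priors on variances. Location parameters are updated one at a
// time (genetic effects as 2x2 animal blocks); variances from their scaled
// inverse chi-square / inverse Wishart full conditionals.
//
// The internal RNG is a Mersenne twister seeded from R's RNG stream, so
// set.seed() in R still makes whole chains reproducible.
//
// Sparse inputs: S in record-major CSR (srow_*), A^-1 in CSC (Ap/Ai/Ax,
// full symmetric pattern). pen/animal are 0-based maps per record.

namespace {

struct Rng {
  std::mt19937_64 gen;
  std::normal_distribution<double> norm;
  explicit Rng(uint64_t seed) : gen(seed), norm(0.0, 1.0) {}
  double rnorm() { return norm(gen); }
  double rchisq(double df) {
    std::gamma_distribution<double> g(df / 2.0, 2.0);
    return g(gen);
  }
};

inline double draw_var(Rng& rng, double ss, double df, double upper) {
  // flat prior on the variance: sig2 = ss / chisq(df)
  double x = rng.rchisq(df);
  if (x < 1e-300) x = 1e-300;
  double v = ss / x;
  if (v > upper) v = upper;
  if (v < 1e-12) v = 1e-12;
  return v;
}

// CSR adjacency built once before the chain
struct Adj {
  std::vector<int> ptr, idx;
  std::vector<double> val;
};

}  // namespace

// [[Rcpp::export]]
List ige_gibbs_cpp(const arma::vec& y, const arma::mat& X,
                   const IntegerVector& pen, const IntegerVector& animal,
                   const IntegerVector& srow_ptr, const IntegerVector& srow_col,
                   const NumericVector& srow_val,
                   const IntegerVector& Ap, const IntegerVector& Ai,
                   const NumericVector& Ax,
                   int n_pens, int q,
                   int n_iter, int burn_in, int thin,
                   bool social, bool use_pen, bool use_genetic,
                   const List& start, double var_upper) {
  const int n = y.n_elem, p = X.n_cols;
  const bool has_social_rows = srow_ptr.size() > 0;

  // seed the internal RNG from R's stream (reproducible via set.seed)
  Rng rng(static_cast<uint64_t>(unif_rand() * 4294967296.0) * 2654435761ULL +
          static_cast<uint64_t>(unif_rand() * 4294967296.0));

  // record lists per pen (CSR)
  Adj penA;
  if (use_pen) {
    std::vector<int> cnt(n_pens, 0);
    for (int i = 0; i < n; ++i) ++cnt[pen[i]];
    penA.ptr.assign(n_pens + 1, 0);
    for (int j = 0; j < n_pens; ++j) penA.ptr[j + 1] = penA.ptr[j] + cnt[j];
    penA.idx.resize(n);
    std::vector<int> at(penA.ptr.begin(), penA.ptr.end() - 1);
    for (int i = 0; i < n; ++i) penA.idx[at[pen[i]]++] = i;
  }

  // per animal: own records, and (record, coef) social appearances (CSR)
  Adj ownA, socA;
  if (use_genetic) {
    std::vector<int> cnt(q, 0);
    for (int i = 0; i < n; ++i) ++cnt[animal[i]];
    ownA.ptr.assign(q + 1, 0);
    for (int a = 0; a < q; ++a) ownA.ptr[a + 1] = ownA.ptr[a] + cnt[a];
    ownA.idx.resize(n);
    std::vector<int> at(ownA.ptr.begin(), ownA.ptr.end() - 1);
    for (int i = 0; i < n; ++i) ownA.idx[at[animal[i]]++] = i;
    if (social && has_social_rows) {
      std::vector<int> scnt(q, 0);
      for (int k = 0; k < srow_col.size(); ++k) ++scnt[srow_col[k]];
      socA.ptr.assign(q + 1, 0);
      for (int a = 0; a < q; ++a) socA.ptr[a + 1] = socA.ptr[a] + scnt[a];
      socA.idx.resize(srow_col.size());
      socA.val.resize(srow_col.size());
      std::vector<int> sat(socA.ptr.begin(), socA.ptr.end() - 1);
      for (int i = 0; i < n; ++i)
        for (int k = srow_ptr[i]; k < srow_ptr[i + 1]; ++k) {
          const int a = srow_col[k];
          socA.idx[sat[a]] = i;
          socA.val[sat[a]] = srow_val[k];
          ++sat[a];
        }
    }
  }

  arma::vec xsq(p);
  for (int j = 0; j < p; ++j) xsq[j] = arma::dot(X.col(j), X.col(j));

  // state
  arma::vec b = as<arma::vec>(start["b"]);
  arma::vec up = use_pen ? as<arma::vec>(start["pen"]) : arma::vec();
  arma::vec aD = use_genetic ? as<arma::vec>(start["aD"]) : arma::vec();
  arma::vec aS = (use_genetic && social) ? as<arma::vec>(start["aS"])
                                         : arma::vec();
  double s2e = as<double>(start["sigma2_e"]);
  double s2p = use_pen ? as<double>(start["sigma2_pen"]) : 0.0;
  arma::mat G(2, 2, arma::fill::eye);
  double s2a = 0.0;
  if (use_genetic) {
    if (social) G = as<arma::mat>(start["G"]);
    else s2a = as<double>(start["sigma2_a"]);
  }

  // residuals given starting state
  arma::vec e = y - X * b;
  if (use_pen) for (int i = 0; i < n; ++i) e[i] -= up[pen[i]];
  if (use_genetic) {
    for (int i = 0; i < n; ++i) e[i] -= aD[animal[i]];
    if (social && has_social_rows)
      for (int i = 0; i < n; ++i)
        for (int k = srow_ptr[i]; k < srow_ptr[i + 1]; ++k)
          e[i] -= srow_val[k] * aS[srow_col[k]];
  }

  const int n_keep = (n_iter - burn_in) / thin;
  const int n_vc = use_genetic ? (social ? 5 : 3) : 2;
  arma::mat vc_out(n_keep, n_vc, arma::fill::zeros);
  arma::vec dev_out(n_keep, arma::fill::zeros);
  arma::vec mb(p, arma::fill::zeros), mp, maD, maS;
  if (use_pen) mp.zeros(n_pens);
  if (use_genetic) { maD.zeros(q); if (social) maS.zeros(q); }
  int kept = 0, g_rejects = 0;

  arma::mat Ginv = social ? arma::mat(arma::inv_sympd(G)) : arma::mat();
  double* ev = e.memptr();

  for (int it = 0; it < n_iter; ++it) {
    // --- fixed effects, single site, flat prior
    for (int j = 0; j < p; ++j) {
      const double rhs = arma::dot(X.col(j), e) + xsq[j] * b[j];
      const double mean = rhs / xsq[j];
      const double sd = std::sqrt(s2e / xsq[j]);
      const double nb = mean + sd * rng.rnorm();
      e -= X.col(j) * (nb - b[j]);
      b[j] = nb;
    }
    // --- pen effects
    if (use_pen) {
      for (int j = 0; j < n_pens; ++j) {
        const int lo = penA.ptr[j], hi = penA.ptr[j + 1];
        double sum = 0.0;
        for (int k = lo; k < hi; ++k) sum += ev[penA.idx[k]];
        const int nj = hi - lo;
        const double prec = nj / s2e + 1.0 / s2p;
        const double mean = (sum + nj * up[j]) / s2e / prec;
        const double nu = mean + std::sqrt(1.0 / prec) * rng.rnorm();
        const double d = nu - up[j];
        for (int k = lo; k < hi; ++k) ev[penA.idx[k]] -= d;
        up[j] = nu;
      }
    }
    // --- genetic effects
    if (use_genetic && social) {
      const double g00 = Ginv(0, 0), g01 = Ginv(0, 1), g11 = Ginv(1, 1);
      for (int a = 0; a < q; ++a) {
        double akk = 0.0, sD = 0.0, sS = 0.0;  // sum_{l != a} Ainv_al a_l
        for (int k = Ap[a]; k < Ap[a + 1]; ++k) {
          const int l = Ai[k];
          if (l == a) akk = Ax[k];
          else { sD += Ax[k] * aD[l]; sS += Ax[k] * aS[l]; }
        }
        double dprecD = 0.0, drhsD = 0.0, dprecS = 0.0, drhsS = 0.0;
        for (int k = ownA.ptr[a]; k < ownA.ptr[a + 1]; ++k) {
          dprecD += 1.0;
          drhsD += ev[ownA.idx[k]] + aD[a];
        }
        for (int k = socA.ptr[a]; k < socA.ptr[a + 1]; ++k) {
          const double c = socA.val[k];
          dprecS += c * c;
          drhsS += c * (ev[socA.idx[k]] + c * aS[a]);
        }
        const double p11 = dprecD / s2e + akk * g00;
        const double p22 = dprecS / s2e + akk * g11;
        const double p12 = akk * g01;
        const double r1 = drhsD / s2e - (g00 * sD + g01 * sS);
        const double r2 = drhsS / s2e - (g01 * sD + g11 * sS);
        const double det = p11 * p22 - p12 * p12;
        const double m1 = (p22 * r1 - p12 * r2) / det;
        const double m2 = (p11 * r2 - p12 * r1) / det;
        const double l11 = std::sqrt(p11);
        const double l21 = p12 / l11;
        const double l22 = std::sqrt(p22 - l21 * l21);
        const double z1 = rng.rnorm(), z2 = rng.rnorm();
        const double x2 = z2 / l22;
        const double x1 = (z1 - l21 * x2) / l11;
        const double nD = m1 + x1, nS = m2 + x2;
        const double dD = nD - aD[a], dS = nS - aS[a];
        for (int k = ownA.ptr[a]; k < ownA.ptr[a + 1]; ++k)
          ev[ownA.idx[k]] -= dD;
        for (int k = socA.ptr[a]; k < socA.ptr[a + 1]; ++k)
          ev[socA.idx[k]] -= socA.val[k] * dS;
        aD[a] = nD; aS[a] = nS;
      }
    } else if (use_genetic) {
      for (int a = 0; a < q; ++a) {
        double akk = 0.0, sD = 0.0;
        for (int k = Ap[a]; k < Ap[a + 1]; ++k) {
          const int l = Ai[k];
          if (l == a) akk = Ax[k]; else sD += Ax[k] * aD[l];
        }
        double dprec = 0.0, drhs = 0.0;
        for (int k = ownA.ptr[a]; k < ownA.ptr[a + 1]; ++k) {
          dprec += 1.0;
          drhs += ev[ownA.idx[k]] + aD[a];
        }
        const double prec = dprec / s2e + akk / s2a;
        const double mean = (drhs / s2e - sD / s2a) / prec;
        const double na = mean + std::sqrt(1.0 / prec) * rng.rnorm();
        const double d = na - aD[a];
        for (int k = ownA.ptr[a]; k < ownA.ptr[a + 1]; ++k)
          ev[ownA.idx[k]] -= d;
        aD[a] = na;
      }
    }
    // --- variances
    const double sse = arma::dot(e, e);
    s2e = draw_var(rng, sse, n - 2.0, var_upper);
    if (use_pen)
      s2p = draw_var(rng, arma::dot(up, up), n_pens - 2.0, var_upper);
    if (use_genetic && !social) {
      double qf = 0.0;
      for (int a = 0; a < q; ++a)
        for (int k = Ap[a]; k < Ap[a + 1]; ++k)
          qf += aD[a] * Ax[k] * aD[Ai[k]];
      s2a = draw_var(rng, qf, q - 2.0, var_upper);
    }
    if (use_genetic && social) {
      // scale matrix Sa: cross products in the A^-1 metric
      double sDD = 0.0, sSS = 0.0, sDS = 0.0;
      for (int a = 0; a < q; ++a)
        for (int k = Ap[a]; k < Ap[a + 1]; ++k) {
          const int l = Ai[k];
          sDD += aD[a] * Ax[k] * aD[l];
          sSS += aS[a] * Ax[k] * aS[l];
          sDS += aD[a] * Ax[k] * aS[l];
        }
      arma::mat Sa = {{sDD, sDS}, {sDS, sSS}};
      const double nu = q - 3.0;  // flat prior on G
      bool ok = false;
      for (int tries = 0; tries < 50 && !ok; ++tries) {
        arma::mat Ls;
        if (!arma::chol(Ls, arma::inv_sympd(Sa), "lower")) break;
        // Bartlett draw: Winv ~ Wishart(nu, Sa^-1); G = Winv^-1
        arma::mat Bm(2, 2, arma::fill::zeros);
        Bm(0, 0) = std::sqrt(rng.rchisq(nu));
        Bm(1, 1) = std::sqrt(rng.rchisq(nu - 1.0));
        Bm(1, 0) = rng.rnorm();
        arma::mat LB = Ls * Bm;
        arma::mat W = LB * LB.t();
        arma::mat Gp;
        if (arma::inv_sympd(Gp, W) &&
            Gp(0, 0) > 1e-12 && Gp(1, 1) > 1e-12 &&
            Gp(0, 0) < var_upper && Gp(1, 1) < var_upper &&
            Gp(0, 0) * Gp(1, 1) - Gp(0, 1) * Gp(0, 1) > 0.0) {
          G = arma::symmatl(Gp);
          ok = true;
        } else {
          ++g_rejects;
        }
      }
      if (ok) Ginv = arma::inv_sympd(G);
      // on repeated failure keep the previous G (counted in g_rejects)
    }
    // --- store
    if (it >= burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      if (use_genetic && social) {
        vc_out(kept, 0) = G(0, 0); vc_out(kept, 1) = G(1, 1);
        vc_out(kept, 2) = G(0, 1); vc_out(kept, 3) = s2p;
        vc_out(kept, 4) = s2e;
      } else if (use_genetic) {
        vc_out(kept, 0) = s2a; vc_out(kept, 1) = s2p; vc_out(kept, 2) = s2e;
      } else {
        vc_out(kept, 0) = s2p; vc_out(kept, 1) = s2e;
      }
      dev_out[kept] = n * std::log(2.0 * M_PI * s2e) + sse / s2e;
      mb += b;
      if (use_pen) mp += up;
      if (use_genetic) { maD += aD; if (social) maS += aS; }
      ++kept;
    }
  }
  if (kept > 0) {
    mb /= kept;
    if (use_pen) mp /= kept;
    if (use_genetic) { maD /= kept; if (social) maS /= kept; }
  }
  return List::create(_["vc"] = vc_out, _["deviance"] = dev_out,
                      _["kept"] = kept, _["g_rejects"] = g_rejects,
                      _["b"] = mb, _["pen"] = mp,
                      _["aD"] = maD, _["aS"] = maS);
}
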