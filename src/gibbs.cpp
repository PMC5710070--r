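// Single-site Gibbs sampler for the random-regression feed-intake models.
//
// Location effects are drawn from their univariate normal full conditionals
// with residual-vector bookkeeping (the residual e = y - W theta is updated in
// place after every draw). Scalar variances use scaled inverse chi-square full
// conditionals; the k x k genetic and permanent covariance matrices use
// inverse-Wishart full conditionals, which with flat (bounded uniform) priors
// have degrees of freedom q - k - 1 (q = number of levels). Draws outside the
// variance bound are rejected and redrawn.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double draw_chisq(double df) { return R::rchisq(df); }

// Inverse-Wishart(nu, S) via Bartlett decomposition of Wishart(nu, S^{-1})
static arma::mat riwish(double nu, const arma::mat& S) {
  const int k = S.n_rows;
  arma::mat Sinv = arma::inv_sympd(arma::symmatu(S));
  arma::mat L = arma::chol(Sinv, "lower");
  arma::mat A(k, k, arma::fill::zeros);
  for (int i = 0; i < k; ++i) {
    A(i, i) = std::sqrt(draw_chisq(nu - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat LA = L * A;
  arma::mat X = LA * LA.t();
  return arma::inv_sympd(arma::symmatu(X));
}

// [[Rcpp::export(name = ".gibbs_chain_cpp")]]
List gibbs_chain_cpp(const arma::vec& y,
                     const arma::ivec& Wp, const arma::ivec& Wi,
                     const arma::vec& Wx,
                     const arma::ivec& col_type,   // 0 fixed, 1 iid, 2 genetic, 3 permanent
                     const arma::ivec& col_iid,    // iid block index per column (-1)
                     const arma::ivec& col_level,  // 0-based animal index
                     const arma::ivec& col_trait,  // 0-based trait index
                     int n_iid,
                     const arma::ivec& Ap, const arma::ivec& Ai,
                     const arma::vec& Ax,          // A-inverse, general CSC
                     int k, int n_anim, int n_perm,
                     int g_off, int p_off,         // 0-based first columns
                     int niter, int burnin, int thin,
                     arma::mat G0, arma::mat P0,
                     double ve, arma::vec iid_var,
                     bool update_resid, double var_max) {
  RNGScope scope;
  const int n = y.n_elem;
  const int p = col_type.n_elem;
  const bool has_gen = n_anim > 0;
  const bool has_perm = n_perm > 0;

  // column sums of squares
  arma::vec csq(p, arma::fill::zeros);
  for (int j = 0; j < p; ++j)
    for (int idx = Wp[j]; idx < Wp[j + 1]; ++idx)
      csq[j] += Wx[idx] * Wx[idx];

  arma::vec theta(p, arma::fill::zeros);
  arma::vec e = y;  // residual at theta = 0
  arma::mat G0inv, P0inv;

  const int ktri = k * (k + 1) / 2;
  int npar = n_iid + 2;  // iid variances + ve + deviance
  if (has_gen) npar += ktri;
  if (has_perm) npar += ktri;
  const int nsave = (niter - burnin) / thin;
  arma::mat samples(nsave, npar, arma::fill::zeros);
  arma::vec theta_sum(p, arma::fill::zeros);
  double ve_sum = 0.0;
  int isave = 0;

  for (int it = 1; it <= niter; ++it) {
    if (has_gen) G0inv = arma::inv_sympd(arma::symmatu(G0));
    if (has_perm) P0inv = arma::inv_sympd(arma::symmatu(P0));

    // ---- location effects ----
    for (int j = 0; j < p; ++j) {
      double prior_prec = 0.0, prior_rhs = 0.0;
      const int tp = col_type[j];
      if (tp == 1) {
        prior_prec = 1.0 / iid_var[col_iid[j]];
      } else if (tp == 2) {
        const int a = col_level[j], r = col_trait[j];
        for (int idx = Ap[a]; idx < Ap[a + 1]; ++idx) {
          const int b = Ai[idx];
          const double v = Ax[idx];
          const double* th = theta.memptr() + g_off + b * k;
          for (int s = 0; s < k; ++s) {
            if (b == a && s == r) continue;
            prior_rhs -= v * G0inv(r, s) * th[s];
          }
          if (b == a) prior_prec += v * G0inv(r, r);
        }
      } else if (tp == 3) {
        const int a = col_level[j], r = col_trait[j];
        prior_prec = P0inv(r, r);
        const double* th = theta.memptr() + p_off + a * k;
        for (int s = 0; s < k; ++s)
          if (s != r) prior_rhs -= P0inv(r, s) * th[s];
      }
      double dot = 0.0;
      for (int idx = Wp[j]; idx < Wp[j + 1]; ++idx)
        dot += Wx[idx] * e[Wi[idx]];
      const double prec = csq[j] / ve + prior_prec;
      if (prec <= 0.0) continue;
      const double rhs = (dot + csq[j] * theta[j]) / ve + prior_rhs;
      const double newv = rhs / prec + R::norm_rand() / std::sqrt(prec);
      const double delta = newv - theta[j];
      if (delta != 0.0) {
        theta[j] = newv;
        for (int idx = Wp[j]; idx < Wp[j + 1]; ++idx)
          e[Wi[idx]] -= Wx[idx] * delta;
      }
    }

    // ---- variances ----
    double SS = arma::dot(e, e);
    if (update_resid) {
      for (int tries = 0; tries < 100; ++tries) {
        double cand = SS / draw_chisq((double)n - 2.0);
        if (cand < var_max) { ve = cand; break; }
      }
    }
    for (int b = 0; b < n_iid; ++b) {
      double ssb = 0.0; int qb = 0;
      for (int j = 0; j < p; ++j)
        if (col_type[j] == 1 && col_iid[j] == b) { ssb += theta[j] * theta[j]; ++qb; }
      for (int tries = 0; tries < 100; ++tries) {
        double cand = ssb / draw_chisq((double)qb - 2.0);
        if (cand < var_max) { iid_var[b] = cand; break; }
      }
    }
    if (has_gen) {
      arma::mat S(k, k, arma::fill::zeros);
      for (int a = 0; a < n_anim; ++a) {
        const double* tha = theta.memptr() + g_off + a * k;
        for (int idx = Ap[a]; idx < Ap[a + 1]; ++idx) {
          const int b = Ai[idx];
          const double v = Ax[idx];
          const double* thb = theta.memptr() + g_off + b * k;
          for (int r = 0; r < k; ++r)
            for (int s = 0; s < k; ++s)
              S(r, s) += v * thb[r] * tha[s];
        }
      }
      S = arma::symmatu((S + S.t()) / 2.0);
      const double nu = (double)n_anim - k - 1.0;
      for (int tries = 0; tries < 100; ++tries) {
        arma::mat cand;
        bool ok = true;
        try { cand = riwish(nu, S); } catch (...) { ok = false; }
        if (ok && cand.max() < var_max) { G0 = cand; break; }
      }
    }
    if (has_perm) {
      arma::mat S(k, k, arma::fill::zeros);
      for (int a = 0; a < n_perm; ++a) {
        const double* th = theta.memptr() + p_off + a * k;
        for (int r = 0; r < k; ++r)
          for (int s = 0; s < k; ++s)
            S(r, s) += th[r] * th[s];
      }
      const double nu = (double)n_perm - k - 1.0;
      for (int tries = 0; tries < 100; ++tries) {
        arma::mat cand;
        bool ok = true;
        try { cand = riwish(nu, S); } catch (...) { ok = false; }
        if (ok && cand.max() < var_max) { P0 = cand; break; }
      }
    }

    // ---- retain ----
    if (it > burnin && (it - burnin) % thin == 0) {
      int c = 0;
      if (has_gen)
        for (int r = 0; r < k; ++r)
          for (int s = r; s < k; ++s) samples(isave, c++) = G0(r, s);
      if (has_perm)
        for (int r = 0; r < k; ++r)
          for (int s = r; s < k; ++s) samples(isave, c++) = P0(r, s);
      for (int b = 0; b < n_iid; ++b) samples(isave, c++) = iid_var[b];
      samples(isave, c++) = ve;
      samples(isave, c++) = (double)n * std::log(2.0 * M_PI * ve) + SS / ve;
      theta_sum += theta;
      ve_sum += ve;
      ++isave;
    }
    if (it % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["samples"] = samples,
    _["theta_mean"] = theta_sum / std::max(isave, 1),
    _["ve_mean"] = ve_sum / std::max(isave, 1),
    _["n_saved"] = isave);
}
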