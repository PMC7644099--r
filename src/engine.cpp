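// Marginal likelihood (and gradient) of the concatenated observation vector
// after analytic integration of all latent Gaussian-process effects.
//
// The covariance is Sigma = sum_g M_g o K_g(hp_g) + s2y * diag(w) + jitter,
// where M_g is a (weighted) incidence mask saying which pairs of rows share
// the g-th group's latent function, K_g is the RBF kernel on the model-time
// grid, and w are per-row noise weights.  An optional "contrast" block adds
// the likelihood of within-cell replicate contrasts, which under the model
// are iid N(0, K_rep + s2y I); their sufficient statistic is the scatter
// matrix S.  Gradients are with respect to log-hyperparameters.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG2PI = 1.8378770664093454836;

// dialect 1: k = s2 * exp(-d2 / ell)          (as printed in the model)
// dialect 2: k = s2 * exp(-d2 / (2 ell^2))    (squared-lengthscale convention)
static inline double rate_of(double ell, int dialect) {
  return dialect == 1 ? 1.0 / ell : 1.0 / (2.0 * ell * ell);
}
// d(rate)/d(log ell) = -cfac * rate
static inline double cfac_of(int dialect) { return dialect == 1 ? 1.0 : 2.0; }

// Cholesky with escalating jitter, relative to s2y. Returns achieved jitter
// or -1 on failure.
static double chol_jitter(mat& L, const mat& A, double s2y) {
  double jit = 1e-8 * s2y;
  const double cap = 1e-4 * s2y * 1.0000001;
  while (jit <= cap) {
    mat Aj = A;
    Aj.diag() += jit;
    if (chol(L, Aj, "lower")) return jit;
    jit *= 10.0;
  }
  return -1.0;
}

// [[Rcpp::export(name = ".eng_eval")]]
Rcpp::List eng_eval(const arma::vec& u,
                    const arma::mat& D2,
                    const Rcpp::List& masks,
                    const arma::vec& noise_w,
                    const Rcpp::List& contrasts,
                    int rep_idx,
                    const arma::vec& hp,
                    int dialect,
                    bool want_grad) {
  const int n = u.n_elem;
  const int G = masks.size();
  const int npar = 2 * G + 1;
  const double s2y = hp(npar - 1);

  vec grad(npar, fill::zeros);

  mat Sigma(n, n, fill::zeros);
  std::vector<mat> Kg(G);
  for (int g = 0; g < G; ++g) {
    const double s2 = hp(2 * g), ell = hp(2 * g + 1);
    const double r = rate_of(ell, dialect);
    mat M = Rcpp::as<mat>(masks[g]);
    Kg[g] = M % (s2 * exp(-r * D2));
    Sigma += Kg[g];
  }
  Sigma.diag() += s2y * noise_w;

  mat L;
  if (!Sigma.is_finite()) {
    return Rcpp::List::create(Rcpp::Named("ll") = R_NegInf,
                              Rcpp::Named("grad") = grad,
                              Rcpp::Named("ok") = false);
  }
  const double jit = chol_jitter(L, Sigma, s2y);
  if (jit < 0.0) {
    return Rcpp::List::create(Rcpp::Named("ll") = R_NegInf,
                              Rcpp::Named("grad") = grad,
                              Rcpp::Named("ok") = false);
  }

  vec a;
  if (!solve(a, trimatl(L), u, solve_opts::no_approx)) {
    return Rcpp::List::create(Rcpp::Named("ll") = R_NegInf,
                              Rcpp::Named("grad") = grad,
                              Rcpp::Named("ok") = false);
  }
  double ll = -0.5 * (n * LOG2PI + 2.0 * accu(log(L.diag())) + dot(a, a));

  if (want_grad) {
    mat Li = inv(trimatl(L));
    mat Si = Li.t() * Li;        // Sigma^{-1}
    vec alpha = Li.t() * a;      // Sigma^{-1} u
    mat W = alpha * alpha.t() - Si;
    for (int g = 0; g < G; ++g) {
      const double ell = hp(2 * g + 1);
      const double r = rate_of(ell, dialect);
      grad(2 * g) = 0.5 * accu(W % Kg[g]);
      grad(2 * g + 1) = 0.5 * cfac_of(dialect) * r * accu(W % Kg[g] % D2);
    }
    grad(npar - 1) = 0.5 * s2y * dot(W.diag(), noise_w) + 0.5 * jit * trace(W);
  }

  // Replicate contrasts: for each shared-grid block, m iid vectors with
  // covariance V = K_rep + s2y I and scatter matrix S.
  const int nc = contrasts.size();
  for (int b = 0; b < nc; ++b) {
    Rcpp::List cb = contrasts[b];
    mat S = Rcpp::as<mat>(cb["S"]);
    double m = Rcpp::as<double>(cb["m"]);
    mat D2c = Rcpp::as<mat>(cb["D2"]);
    const int T = S.n_rows;

    mat V(T, T, fill::zeros);
    mat Kyc;
    if (rep_idx > 0) {
      const double s2r = hp(2 * (rep_idx - 1));
      const double ellr = hp(2 * (rep_idx - 1) + 1);
      Kyc = s2r * exp(-rate_of(ellr, dialect) * D2c);
      V += Kyc;
    }
    V.diag() += s2y;

    mat Lc;
    if (!V.is_finite()) {
      return Rcpp::List::create(Rcpp::Named("ll") = R_NegInf,
                                Rcpp::Named("grad") = grad,
                                Rcpp::Named("ok") = false);
    }
    const double jitc = chol_jitter(Lc, V, s2y);
    if (jitc < 0.0) {
      return Rcpp::List::create(Rcpp::Named("ll") = R_NegInf,
                                Rcpp::Named("grad") = grad,
                                Rcpp::Named("ok") = false);
    }
    mat Lci = inv(trimatl(Lc));
    mat Vi = Lci.t() * Lci;
    double ldet = 2.0 * accu(log(Lc.diag()));
    ll += -0.5 * (m * (T * LOG2PI + ldet) + accu(Vi % S));

    if (want_grad) {
      mat M2 = Vi * S * Vi;
      mat Wc = M2 - m * Vi;      // d ll = 0.5 * tr(Wc dV)
      if (rep_idx > 0) {
        const double ellr = hp(2 * (rep_idx - 1) + 1);
        const double rr = rate_of(ellr, dialect);
        grad(2 * (rep_idx - 1)) += 0.5 * accu(Wc % Kyc);
        grad(2 * (rep_idx - 1) + 1) +=
          0.5 * cfac_of(dialect) * rr * accu(Wc % Kyc % D2c);
      }
      grad(npar - 1) += 0.5 * (s2y + jitc) * trace(Wc);
    }
  }

  return Rcpp::List::create(Rcpp::Named("ll") = ll,
                            Rcpp::Named("grad") = grad,
                            Rcpp::Named("ok") = true);
}
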