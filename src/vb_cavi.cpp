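// Mean-field variational inference for the dense Gaussian weighted
// stochastic block model.
//
// Model: for every unordered vertex pair i<j, A_ij ~ N(mu_{z_i z_j},
// sigma2_{z_i z_j}); z_i iid uniform over {1..K}. Each unique block pair
// (a<=b) carries a conjugate normal-inverse-gamma prior
//   sigma2 ~ IG(alpha0, beta0),  mu | sigma2 ~ N(m0, sigma2/kappa0),
// the conjugate exponential family for the natural parameters
// eta_ab = (mu/sigma2, -1/sigma2, -mu^2/sigma2).
//
// Two coordinate-ascent schemes share one code path; both update the
// responsibilities q_i(z_i) sequentially node by node (so the objective is
// provably non-decreasing) and both compute the same conjugate NIG
// posterior from responsibility-weighted sufficient statistics (N, S1, S2)
// per block pair:
//
//  - plugin = true ("variational EM", the default upstream): label updates
//    score edges with the MAP block parameters (mu = m, sigma2 =
//    beta/(alpha + 3/2), the joint NIG maximizer); the objective is the
//    EM lower bound  E_q[log p(A, z | theta_hat)] + H(q) + log p(theta_hat).
//    Overfitted communities survive as local optima, which the
//    valid-solution bookkeeping of the K-selection procedure relies on.
//
//  - plugin = false (full VB): label updates use expected log densities
//    under the NIG factor, E[log N(x|block)] = -0.5 log 2pi
//    + 0.5(digamma(alpha) - log beta) - 0.5((alpha/beta)(x-m)^2 + 1/kappa);
//    the objective is the ELBO with exact NIG KL terms. The per-edge
//    -1/(2 kappa) and digamma corrections act as a complexity penalty that
//    aggressively empties surplus communities.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double LOG2PI = 1.8378770664093454836;

// KL( NIG(m,k,a,b) || NIG(m0,k0,a0,b0) )
static double kl_nig(double m, double k, double a, double b,
                     double m0, double k0, double a0, double b0) {
  double e_inv_s2 = a / b;
  double kl_norm = 0.5 * std::log(k / k0) - 0.5 +
    0.5 * k0 * (1.0 / k + (m - m0) * (m - m0) * e_inv_s2);
  double kl_ig = (a - a0) * R::digamma(a) - std::lgamma(a) +
    std::lgamma(a0) + a0 * (std::log(b) - std::log(b0)) +
    a * (b0 - b) / b;
  return kl_norm + kl_ig;
}

// log NIG(mu, s2 | m0, k0, a0, b0)
static double log_nig(double mu, double s2,
                      double m0, double k0, double a0, double b0) {
  double lnorm = -0.5 * (LOG2PI + std::log(s2 / k0)) -
    0.5 * k0 * (mu - m0) * (mu - m0) / s2;
  double lig = a0 * std::log(b0) - std::lgamma(a0) -
    (a0 + 1.0) * std::log(s2) - b0 / s2;
  return lnorm + lig;
}

// [[Rcpp::export]]
Rcpp::List vb_cavi(const arma::mat& A, arma::mat R,
                   double m0, double kappa0, double alpha0, double beta0,
                   int max_iter, double tol, bool plugin) {
  const int n = A.n_rows;
  const int K = R.n_cols;
  const mat A2 = square(A);

  mat M1 = A * R;            // n x K: sum_j A_ij r_jl (diag(A) is zero)
  mat M2 = A2 * R;
  rowvec M0 = sum(R, 0);     // 1 x K

  // q(eta) / posterior parameters, symmetric K x K over block pairs
  mat qm(K, K), qk(K, K), qa(K, K), qb(K, K);
  mat Nw(K, K), S1(K, K), S2(K, K);

  auto eta_update = [&]() {
    mat G0 = R.t() * R;
    mat G1 = R.t() * A * R;
    mat G2 = R.t() * A2 * R;
    for (int a = 0; a < K; ++a) {
      for (int b = a; b < K; ++b) {
        double N, s1, s2;
        if (a == b) {
          N  = 0.5 * (M0(a) * M0(a) - G0(a, a));
          s1 = 0.5 * G1(a, a);
          s2 = 0.5 * G2(a, a);
        } else {
          N  = M0(a) * M0(b) - G0(a, b);
          s1 = G1(a, b);
          s2 = G2(a, b);
        }
        if (N < 0) N = 0;  // numerical guard
        double kk = kappa0 + N;
        double mm = (kappa0 * m0 + s1) / kk;
        double aa = alpha0 + 0.5 * N;
        double bb = beta0 + 0.5 * (s2 + kappa0 * m0 * m0 - kk * mm * mm);
        if (bb < 1e-12) bb = 1e-12;
        Nw(a, b) = Nw(b, a) = N;
        S1(a, b) = S1(b, a) = s1;
        S2(a, b) = S2(b, a) = s2;
        qm(a, b) = qm(b, a) = mm;
        qk(a, b) = qk(b, a) = kk;
        qa(a, b) = qa(b, a) = aa;
        qb(a, b) = qb(b, a) = bb;
      }
    }
  };

  // per-block expected (or plug-in) log-precision, precision, and the
  // extra per-edge variance term (1/kappa under full VB, 0 under plug-in)
  mat elog_prec(K, K), e_prec(K, K), extra(K, K);
  auto refresh_coefs = [&]() {
    for (int a = 0; a < K; ++a)
      for (int b = 0; b < K; ++b) {
        if (plugin) {
          double s2hat = qb(a, b) / (qa(a, b) + 1.5);
          elog_prec(a, b) = -std::log(s2hat);
          e_prec(a, b) = 1.0 / s2hat;
          extra(a, b) = 0.0;
        } else {
          elog_prec(a, b) = R::digamma(qa(a, b)) - std::log(qb(a, b));
          e_prec(a, b) = qa(a, b) / qb(a, b);
          extra(a, b) = 1.0 / qk(a, b);
        }
      }
  };

  // entropy-plus-label-prior term shared by both objectives
  auto z_term = [&]() {
    double e_z = 0.0;
    const double logpi = -std::log((double)K);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < K; ++k) {
        double r = R(i, k);
        if (r > 0) e_z += r * (logpi - std::log(r));
      }
    return e_z;
  };

  // full-VB evidence lower bound at the current (R, NIG posterior) state;
  // a valid ELBO whichever scheme produced the state
  auto elbo_now = [&]() {
    double e_lik = 0.0, kl = 0.0;
    for (int a = 0; a < K; ++a) {
      for (int b = a; b < K; ++b) {
        double quad = S2(a, b) - 2.0 * qm(a, b) * S1(a, b) +
          qm(a, b) * qm(a, b) * Nw(a, b);
        double elog = R::digamma(qa(a, b)) - std::log(qb(a, b));
        e_lik += Nw(a, b) * 0.5 * (elog - LOG2PI) -
          0.5 * ((qa(a, b) / qb(a, b)) * quad + Nw(a, b) / qk(a, b));
        kl += kl_nig(qm(a, b), qk(a, b), qa(a, b), qb(a, b),
                     m0, kappa0, alpha0, beta0);
      }
    }
    return e_lik + z_term() - kl;
  };

  // EM lower bound E_q[log p(A, z | theta_hat)] + H(q) + log p(theta_hat)
  // at the MAP parameters of the current posterior
  auto objective = [&]() {
    if (!plugin) return elbo_now();
    double e_lik = 0.0, param_term = 0.0;
    for (int a = 0; a < K; ++a) {
      for (int b = a; b < K; ++b) {
        double quad = S2(a, b) - 2.0 * qm(a, b) * S1(a, b) +
          qm(a, b) * qm(a, b) * Nw(a, b);
        double s2hat = qb(a, b) / (qa(a, b) + 1.5);
        e_lik += Nw(a, b) * 0.5 * (-std::log(s2hat) - LOG2PI) -
          0.5 * quad / s2hat;
        param_term += log_nig(qm(a, b), s2hat, m0, kappa0, alpha0, beta0);
      }
    }
    return e_lik + z_term() + param_term;
  };

  eta_update();
  std::vector<double> trace;
  bool converged = false;

  for (int iter = 1; iter <= max_iter; ++iter) {
    refresh_coefs();
    // coefficient matrices: log edge score = C1 + C2 * x - 0.5 * C3 * x^2
    mat cmat = 0.5 * (elog_prec - LOG2PI) - 0.5 * extra;
    mat C1 = cmat - 0.5 * (e_prec % square(qm));
    mat C2 = e_prec % qm;
    mat C3 = e_prec;

    // sequential z-sweep
    for (int i = 0; i < n; ++i) {
      rowvec ri = R.row(i);
      rowvec T0 = M0 - ri;
      rowvec T1 = M1.row(i);
      rowvec T2 = M2.row(i);
      vec logrho = C1 * T0.t() + C2 * T1.t() - 0.5 * (C3 * T2.t());
      logrho -= logrho.max();
      vec newr = exp(logrho);
      newr /= accu(newr);
      rowvec delta = newr.t() - ri;
      M0 += delta;
      M1 += A.col(i) * delta;
      M2 += A2.col(i) * delta;
      R.row(i) = newr.t();
    }

    eta_update();
    double obj = objective();
    trace.push_back(obj);
    size_t m = trace.size();
    if (m > 1) {
      double prev = trace[m - 2];
      if (std::abs(obj - prev) < tol * (std::abs(prev) + tol)) {
        converged = true;
        break;
      }
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("responsibilities") = R,
    Rcpp::Named("elbo") = elbo_now(),
    Rcpp::Named("mu") = qm,
    Rcpp::Named("sigma2") = qb / (qa - 1.0),
    Rcpp::Named("post_m") = qm, Rcpp::Named("post_kappa") = qk,
    Rcpp::Named("post_alpha") = qa, Rcpp::Named("post_beta") = qb,
    Rcpp::Named("objective_trace") = trace,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("n_iter") = (int)trace.size());
}
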