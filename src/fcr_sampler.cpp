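#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the Bayesian LASSO forward
// continuation ratio model with variable inclusion indicators:
//
//   pi_ik = 1 - exp(-exp(alpha_k + x_i' D_gamma beta))
//   alpha_k ~ Normal(0, sigma2)
//   beta_m | lambda ~ Laplace(0, 1/lambda)
//   lambda ~ Gamma(a, b)  (rate parameterization)
//   gamma_m ~ Bernoulli(s)
//
// The likelihood is the Bernoulli form over long-format at-risk records
// (subject i, interval k, response y). Updates per sweep: adaptive
// random-walk Metropolis for each alpha_k and each active beta_m, a
// direct Laplace prior draw for inactive beta_m (their exact full
// conditional), the exact Bernoulli full conditional for each gamma_m,
// and the exact conjugate Gamma(a + P, b + sum|beta|) draw for lambda.
// Proposal scales adapt (Robbins-Monro towards 0.44 acceptance) during
// the adaptation phase only and are frozen afterwards, so the retained
// draws come from a time-homogeneous Markov chain.

static const double LP_CLAMP = 30.0;

// Bernoulli log-density of one at-risk record under the clog-log hazard:
// y = 0 contributes log(1 - pi) = -exp(lp); y = 1 contributes
// log pi = log(-expm1(-exp(lp))), with log pi -> lp as exp(lp) -> 0.
static inline double rec_loglik(double lp, int y) {
  if (lp > LP_CLAMP) lp = LP_CLAMP;
  if (lp < -LP_CLAMP) lp = -LP_CLAMP;
  double t = std::exp(lp);
  if (!y) return -t;
  return (t < 1e-10) ? lp : std::log(-std::expm1(-t));
}

struct Records {
  std::vector<int> i, k, y;
  std::vector<std::vector<int> > by_k; // record indices per interval
  int n_rec;
};

static double loglik_all(const Records &R, const std::vector<double> &alpha,
                         const std::vector<double> &eta) {
  double ll = 0.0;
  for (int r = 0; r < R.n_rec; ++r) {
    ll += rec_loglik(alpha[R.k[r]] + eta[R.i[r]], R.y[r]);
  }
  return ll;
}

// full log-likelihood when covariate column x gets coefficient shift d
static double loglik_shift(const Records &R, const std::vector<double> &alpha,
                           const std::vector<double> &eta, const double *x,
                           double d) {
  double ll = 0.0;
  for (int r = 0; r < R.n_rec; ++r) {
    int i = R.i[r];
    ll += rec_loglik(alpha[R.k[r]] + eta[i] + d * x[i], R.y[r]);
  }
  return ll;
}

// partial log-likelihood of interval kk under threshold value a_k
static double loglik_interval(const Records &R, int kk, double a_k,
                              const std::vector<double> &eta) {
  double ll = 0.0;
  const std::vector<int> &idx = R.by_k[kk];
  for (size_t j = 0; j < idx.size(); ++j) {
    int r = idx[j];
    ll += rec_loglik(a_k + eta[R.i[r]], R.y[r]);
  }
  return ll;
}

static inline double rlaplace(double scale) {
  double e = R::rexp(scale);
  return (R::unif_rand() < 0.5) ? -e : e;
}

// [[Rcpp::export]]
List fcr_blasso_chain(IntegerVector rec_i, IntegerVector rec_k,
                      IntegerVector rec_y, NumericMatrix X, int K,
                      double a, double b, double s, double sigma2,
                      bool fix_gamma, double fixed_lambda, bool prior_only,
                      int n_adapt, int n_burnin, int n_save, int thin,
                      NumericVector alpha0, NumericVector beta0,
                      IntegerVector gamma0, double lambda0) {
  const int N = X.nrow(), P = X.ncol();
  const bool lambda_free = !R_finite(fixed_lambda) || fixed_lambda <= 0.0;

  Records R;
  R.n_rec = rec_i.size();
  R.i.assign(rec_i.begin(), rec_i.end());
  R.k.assign(rec_k.begin(), rec_k.end());
  R.y.assign(rec_y.begin(), rec_y.end());
  R.by_k.resize(K);
  for (int r = 0; r < R.n_rec; ++r) R.by_k[R.k[r]].push_back(r);

  std::vector<double> alpha(alpha0.begin(), alpha0.end());
  std::vector<double> beta(beta0.begin(), beta0.end());
  std::vector<int> gam(gamma0.begin(), gamma0.end());
  double lambda = lambda_free ? lambda0 : fixed_lambda;
  if (fix_gamma) std::fill(gam.begin(), gam.end(), 1);

  std::vector<double> eta(N, 0.0);
  for (int m = 0; m < P; ++m) {
    if (gam[m] && beta[m] != 0.0) {
      const double *x = &X(0, m);
      for (int i = 0; i < N; ++i) eta[i] += beta[m] * x[i];
    }
  }
  double L_cur = prior_only ? 0.0 : loglik_all(R, alpha, eta);

  std::vector<double> ls_alpha(K, std::log(0.5)), ls_beta(P, std::log(0.25));
  std::vector<long> acc_alpha(K, 0), try_alpha(K, 0);
  std::vector<long> acc_beta(P, 0), try_beta(P, 0);
  std::vector<long> adapt_t_alpha(K, 0), adapt_t_beta(P, 0);
  const double target = 0.44, prior_odds_log = std::log((1.0 - s) / s);

  NumericMatrix out_alpha(n_save, K), out_beta(n_save, P);
  IntegerMatrix out_gamma(n_save, P);
  NumericVector out_lambda(n_save), out_loglik(n_save);

  const int n_total = n_adapt + n_burnin + n_save * thin;
  int saved = 0;

  for (int it = 0; it < n_total; ++it) {
    bool adapting = it < n_adapt;

    // (i) thresholds alpha_k: random-walk Metropolis, Normal(0, sigma2) prior
    for (int k = 0; k < K; ++k) {
      double cur = alpha[k];
      double prop = cur + std::exp(ls_alpha[k]) * R::norm_rand();
      double d_lik = 0.0;
      double part_cur = 0.0, part_prop = 0.0;
      if (!prior_only) {
        part_cur = loglik_interval(R, k, cur, eta);
        part_prop = loglik_interval(R, k, prop, eta);
        d_lik = part_prop - part_cur;
      }
      double d_prior = -(prop * prop - cur * cur) / (2.0 * sigma2);
      bool acc = std::log(R::unif_rand()) < d_lik + d_prior;
      if (acc) {
        alpha[k] = prop;
        L_cur += d_lik;
      }
      ++try_alpha[k];
      if (acc) ++acc_alpha[k];
      if (adapting) {
        ++adapt_t_alpha[k];
        ls_alpha[k] += (acc ? (1.0 - target) : -target) /
                       std::sqrt((double)adapt_t_alpha[k]);
      }
    }

    // (ii) coefficients beta_m
    for (int m = 0; m < P; ++m) {
      if (!gam[m]) {
        // likelihood free of beta_m: exact full conditional is the prior
        beta[m] = rlaplace(1.0 / lambda);
        continue;
      }
      double cur = beta[m];
      double prop = cur + std::exp(ls_beta[m]) * R::norm_rand();
      double L_prop = L_cur, d_lik = 0.0;
      if (!prior_only) {
        L_prop = loglik_shift(R, alpha, eta, &X(0, m), prop - cur);
        d_lik = L_prop - L_cur;
      }
      double d_prior = -lambda * (std::fabs(prop) - std::fabs(cur));
      bool acc = std::log(R::unif_rand()) < d_lik + d_prior;
      if (acc) {
        const double *x = &X(0, m);
        double d = prop - cur;
        for (int i = 0; i < N; ++i) eta[i] += d * x[i];
        beta[m] = prop;
        L_cur = L_prop;
      }
      ++try_beta[m];
      if (acc) ++acc_beta[m];
      if (adapting) {
        ++adapt_t_beta[m];
        ls_beta[m] += (acc ? (1.0 - target) : -target) /
                      std::sqrt((double)adapt_t_beta[m]);
      }
    }

    // (iii) inclusion indicators gamma_m: exact Bernoulli full conditional
    if (!fix_gamma) {
      for (int m = 0; m < P; ++m) {
        double L1, L0;
        if (prior_only) {
          L1 = L0 = 0.0;
        } else if (gam[m]) {
          L1 = L_cur;
          L0 = loglik_shift(R, alpha, eta, &X(0, m), -beta[m]);
        } else {
          L0 = L_cur;
          L1 = loglik_shift(R, alpha, eta, &X(0, m), beta[m]);
        }
        // p(gamma=1 | rest) = 1 / (1 + ((1-s)/s) L0/L1)
        double p1 = 1.0 / (1.0 + std::exp(prior_odds_log + L0 - L1));
        int newg = (R::unif_rand() < p1) ? 1 : 0;
        if (newg != gam[m]) {
          const double *x = &X(0, m);
          double d = newg ? beta[m] : -beta[m];
          for (int i = 0; i < N; ++i) eta[i] += d * x[i];
          L_cur = newg ? L1 : L0;
          gam[m] = newg;
        }
      }
    }

    // (iv) penalty lambda: conjugate Gamma(a + P, b + sum |beta_m|)
    if (lambda_free) {
      double sab = 0.0;
      for (int m = 0; m < P; ++m) sab += std::fabs(beta[m]);
      lambda = R::rgamma(a + P, 1.0 / (b + sab)); // R::rgamma uses scale
    }

    if (it >= n_adapt + n_burnin && ((it - n_adapt - n_burnin + 1) % thin == 0)) {
      for (int k = 0; k < K; ++k) out_alpha(saved, k) = alpha[k];
      for (int m = 0; m < P; ++m) {
        out_beta(saved, m) = beta[m];
        out_gamma(saved, m) = gam[m];
      }
      out_lambda[saved] = lambda;
      out_loglik[saved] = L_cur;
      ++saved;
    }
    if ((it & 255) == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector ar_alpha(K), ar_beta(P);
  for (int k = 0; k < K; ++k)
    ar_alpha[k] = try_alpha[k] ? (double)acc_alpha[k] / try_alpha[k] : NA_REAL;
  for (int m = 0; m < P; ++m)
    ar_beta[m] = try_beta[m] ? (double)acc_beta[m] / try_beta[m] : NA_REAL;

  return List::create(
      _["alpha"] = out_alpha, _["beta"] = out_beta, _["gamma"] = out_gamma,
      _["lambda"] = out_lambda, _["loglik"] = out_loglik,
      _["accept_alpha"] = ar_alpha, _["accept_beta"] = ar_beta);
}
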