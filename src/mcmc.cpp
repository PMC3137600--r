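// Adaptive Metropolis-within-Gibbs sampler for the Bayesian conditional
// logistic regression on matched case/pseudo-control pairs.
//
// Model:  loglik(beta) = sum_i -log(1 + exp(-d_i . beta))
//         beta   ~ MVN(mu, sigma2 * Sigma)
//         sigma2 ~ InverseGamma(a, b)   (conjugate given beta)
//
// beta components are updated by random-walk Metropolis with step sizes
// adapted toward a 0.44 acceptance rate during burn-in; sigma2 is drawn
// from its exact inverse-gamma full conditional.

#include <Rcpp.h>
using namespace Rcpp;

static double cond_loglik(const NumericVector& v) {
  double ll = 0.0;
  for (int i = 0; i < v.size(); ++i) {
    // -log(1 + exp(-v)) computed stably on both tails
    double x = v[i];
    if (x > 0) ll += -log1p(std::exp(-x));
    else       ll += x - log1p(std::exp(x));
  }
  return ll;
}

// (beta - mu)' SigmaInv (beta - mu)
static double quad_form(const NumericVector& beta, const NumericVector& mu,
                        const NumericMatrix& SigmaInv) {
  const int K = beta.size();
  double q = 0.0;
  for (int a = 0; a < K; ++a) {
    double ra = beta[a] - mu[a];
    for (int b = 0; b < K; ++b) q += ra * SigmaInv(a, b) * (beta[b] - mu[b]);
  }
  return q;
}

// [[Rcpp::export(name = ".mcmc_chain")]]
List mcmc_chain(NumericMatrix D, NumericVector mu, NumericMatrix SigmaInv,
                double ig_a, double ig_b, double fixed_sigma2,
                int burnin, int iter, int thin,
                NumericVector beta0, double sigma2_0) {
  const int n = D.nrow(), K = D.ncol();
  const double target = 0.44;
  const bool sample_s2 = fixed_sigma2 <= 0.0;

  NumericVector beta = clone(beta0);
  double sigma2 = sample_s2 ? sigma2_0 : fixed_sigma2;

  NumericVector v(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += D(i, k) * beta[k];
    v[i] = s;
  }
  double ll = cond_loglik(v);
  double qf = quad_form(beta, mu, SigmaInv);

  NumericVector lstep(K, std::log(0.5));
  IntegerVector acc_batch(K), prop_batch(K), acc_keep(K), prop_keep(K);
  int batch = 0;

  const int nkeep = iter / thin;
  NumericMatrix bdraw(nkeep, K);
  NumericVector s2draw(nkeep);
  int kept = 0;

  const int total = burnin + iter;
  for (int it = 0; it < total; ++it) {
    const bool adapting = it < burnin;

    for (int k = 0; k < K; ++k) {
      double step = std::exp(lstep[k]);
      double delta = R::rnorm(0.0, step);
      NumericVector beta_new = clone(beta);
      beta_new[k] = beta[k] + delta;
      NumericVector v_new(n);
      for (int i = 0; i < n; ++i) v_new[i] = v[i] + D(i, k) * delta;
      double ll_new = cond_loglik(v_new);
      double qf_new = quad_form(beta_new, mu, SigmaInv);
      double logr = (ll_new - ll) - 0.5 * (qf_new - qf) / sigma2;
      if (adapting) ++prop_batch[k]; else ++prop_keep[k];
      if (std::log(R::runif(0.0, 1.0)) < logr) {
        beta = beta_new; v = v_new; ll = ll_new; qf = qf_new;
        if (adapting) ++acc_batch[k]; else ++acc_keep[k];
      }
    }

    if (sample_s2) {
      double shape = ig_a + 0.5 * K;
      double rate = ig_b + 0.5 * qf;
      sigma2 = 1.0 / R::rgamma(shape, 1.0 / rate);
    }

    if (adapting && (it + 1) % 50 == 0) {
      ++batch;
      double gain = std::min(0.05, 1.0 / std::sqrt((double)batch));
      for (int k = 0; k < K; ++k) {
        double rate = prop_batch[k] ? (double)acc_batch[k] / prop_batch[k] : 0.0;
        lstep[k] += (rate > target ? gain : -gain);
        acc_batch[k] = prop_batch[k] = 0;
      }
    }

    if (!adapting) {
      int post = it - burnin;
      if ((post + 1) % thin == 0 && kept < nkeep) {
        for (int k = 0; k < K; ++k) bdraw(kept, k) = beta[k];
        s2draw[kept] = sigma2;
        ++kept;
      }
    }
  }

  NumericVector acc(K);
  for (int k = 0; k < K; ++k)
    acc[k] = prop_keep[k] ? (double)acc_keep[k] / prop_keep[k] : NA_REAL;

  return List::create(_["beta"] = bdraw, _["sigma2"] = s2draw,
                      _["accept"] = acc, _["step"] = exp(lstep));
}
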