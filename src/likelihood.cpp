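// Likelihood kernels for the two outcome models. These sit in the innermost
// MCMC loop (thousands of evaluations per fit), so the n-length special
// functions live here rather than in R.
#include <Rcpp.h>
using namespace Rcpp;

// Negative-binomial log likelihood (mean/dispersion parameterisation),
// its derivative u_i = d loglik / d eta_i, and d loglik / d log r.
// [[Rcpp::export]]
List nb_ll_parts(NumericVector y, NumericVector eta, double log_r) {
  const double r = std::exp(std::min(log_r, 10.0));
  const int n = y.size();
  int ymax = 0;
  for (int i = 0; i < n; i++) if (y[i] > ymax) ymax = (int) y[i];
  // counts take few small integer values: tabulate the y-dependent special
  // functions once per evaluation instead of per row
  std::vector<double> A(ymax + 1), D(ymax + 1);
  const double lg_r = R::lgammafn(r), dig_r = R::digamma(r);
  for (int v = 0; v <= ymax; v++) {
    A[v] = R::lgammafn(v + r) - lg_r - R::lgammafn(v + 1.0);
    D[v] = R::digamma(v + r) - dig_r;
  }
  const double logr = std::log(r);
  double ll = 0.0, dlr = 0.0;
  NumericVector u(n);
  for (int i = 0; i < n; i++) {
    const double e = std::min(eta[i], 30.0);
    const double mu = std::exp(e);
    const double yi = y[i];
    const double t = std::log(r + mu);
    ll += A[(int) yi] + r * (logr - t) + yi * (e - t);
    u[i] = yi - mu * (yi + r) / (mu + r);
    dlr += D[(int) yi] + logr + 1.0 - t - (yi + r) / (r + mu);
  }
  return List::create(_["ll"] = ll, _["u"] = u, _["dlr"] = r * dlr);
}

// Bernoulli log likelihood under the complementary-log-log link with the
// exposure already inside eta: P(event) = 1 - exp(-exp(eta)).
// [[Rcpp::export]]
List cloglog_ll_parts(NumericVector y, NumericVector eta) {
  const int n = y.size();
  double ll = 0.0;
  NumericVector u(n);
  for (int i = 0; i < n; i++) {
    double lam = std::exp(std::min(eta[i], 30.0));
    if (lam < 1e-300) lam = 1e-300;
    if (y[i] == 1.0) {
      double em = -std::expm1(-lam);
      if (em < 1e-300) em = 1e-300;
      ll += std::log(em);
      u[i] = lam * std::exp(-lam) / em;
    } else {
      ll += -lam;
      u[i] = -lam;
    }
  }
  return List::create(_["ll"] = ll, _["u"] = u);
}

// Bernoulli log likelihood under the logit link.
// [[Rcpp::export]]
List logit_ll_parts(NumericVector y, NumericVector eta) {
  const int n = y.size();
  double ll = 0.0;
  NumericVector u(n);
  for (int i = 0; i < n; i++) {
    const double p = 1.0 / (1.0 + std::exp(-eta[i]));
    ll += (y[i] == 1.0) ? std::log(std::max(p, 1e-300))
                        : std::log(std::max(1.0 - p, 1e-300));
    u[i] = y[i] - p;
  }
  return List::create(_["ll"] = ll, _["u"] = u);
}
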