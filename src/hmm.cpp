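#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gaussian log-density
static inline double ldnorm(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return -0.5 * z * z - std::log(sd) - 0.918938533204672741780329736406;
}

// One EM (Baum-Welch) pass for a Gaussian-emission HMM.
// Returns gamma (T x K state posteriors), xi_sum (K x K expected
// transition counts) and the scaled-forward log-likelihood.
// [[Rcpp::export]]
List hmm_estep(NumericVector y, NumericVector pi0, NumericMatrix A,
               NumericVector mu, NumericVector sd) {
  const int T = y.size(), K = mu.size();
  NumericMatrix B(T, K);       // emission likelihoods (scaled per frame)
  for (int t = 0; t < T; ++t) {
    double m = R_NegInf;
    for (int k = 0; k < K; ++k) {
      B(t, k) = ldnorm(y[t], mu[k], sd[k]);
      if (B(t, k) > m) m = B(t, k);
    }
    for (int k = 0; k < K; ++k) B(t, k) = std::exp(B(t, k) - m);
  }
  NumericMatrix alpha(T, K), beta(T, K);
  NumericVector c(T);          // scaling factors
  double ll = 0.0;
  // forward
  for (int k = 0; k < K; ++k) alpha(0, k) = pi0[k] * B(0, k);
  c[0] = sum(alpha(0, _));
  for (int k = 0; k < K; ++k) alpha(0, k) /= c[0];
  for (int t = 1; t < T; ++t) {
    double ct = 0;
    for (int k = 0; k < K; ++k) {
      double s = 0;
      for (int j = 0; j < K; ++j) s += alpha(t - 1, j) * A(j, k);
      alpha(t, k) = s * B(t, k);
      ct += alpha(t, k);
    }
    c[t] = ct;
    for (int k = 0; k < K; ++k) alpha(t, k) /= ct;
  }
  // log-lik up to the per-frame max-emission rescaling (constant within
  // an EM fit for fixed data; recomputed exactly in hmm_loglik)
  for (int t = 0; t < T; ++t) ll += std::log(c[t]);
  // backward
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      double s = 0;
      for (int k = 0; k < K; ++k) s += A(j, k) * B(t + 1, k) * beta(t + 1, k);
      beta(t, j) = s / c[t + 1];
    }
  }
  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    double s = 0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); s += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= s;
  }
  NumericMatrix xi(K, K);
  for (int t = 0; t < T - 1; ++t) {
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi(j, k) += alpha(t, j) * A(j, k) * B(t + 1, k) * beta(t + 1, k) / c[t + 1];
  }
  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["ll_scaled"] = ll);
}

// Exact log-likelihood by the scaled forward pass.
// [[Rcpp::export]]
double hmm_loglik(NumericVector y, NumericVector pi0, NumericMatrix A,
                  NumericVector mu, NumericVector sd) {
  const int T = y.size(), K = mu.size();
  std::vector<double> a(K), an(K);
  double ll = 0.0;
  double m = R_NegInf;
  std::vector<double> lb(K);
  for (int k = 0; k < K; ++k) { lb[k] = ldnorm(y[0], mu[k], sd[k]); if (lb[k] > m) m = lb[k]; }
  double ct = 0;
  for (int k = 0; k < K; ++k) { a[k] = pi0[k] * std::exp(lb[k] - m); ct += a[k]; }
  ll += std::log(ct) + m;
  for (int k = 0; k < K; ++k) a[k] /= ct;
  for (int t = 1; t < T; ++t) {
    m = R_NegInf;
    for (int k = 0; k < K; ++k) { lb[k] = ldnorm(y[t], mu[k], sd[k]); if (lb[k] > m) m = lb[k]; }
    ct = 0;
    for (int k = 0; k < K; ++k) {
      double s = 0;
      for (int j = 0; j < K; ++j) s += a[j] * A(j, k);
      an[k] = s * std::exp(lb[k] - m);
      ct += an[k];
    }
    ll += std::log(ct) + m;
    for (int k = 0; k < K; ++k) a[k] = an[k] / ct;
  }
  return ll;
}

// Most likely state path (Viterbi), 1-based state indices.
// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericVector y, NumericVector pi0,
                          NumericMatrix A, NumericVector mu,
                          NumericVector sd) {
  const int T = y.size(), K = mu.size();
  NumericMatrix d(T, K);
  IntegerMatrix psi(T, K);
  const double tiny = -1e300;
  for (int k = 0; k < K; ++k)
    d(0, k) = (pi0[k] > 0 ? std::log(pi0[k]) : tiny) + ldnorm(y[0], mu[k], sd[k]);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = tiny; int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = d(t - 1, j) + (A(j, k) > 0 ? std::log(A(j, k)) : tiny);
        if (v > best) { best = v; arg = j; }
      }
      d(t, k) = best + ldnorm(y[t], mu[k], sd[k]);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(T);
  int arg = 0; double best = tiny;
  for (int k = 0; k < K; ++k) if (d(T - 1, k) > best) { best = d(T - 1, k); arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 1; t > 0; --t) {
    arg = psi(t, arg);
    path[t - 1] = arg + 1;
  }
  return path;
}
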