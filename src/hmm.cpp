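#include <Rcpp.h>
using namespace Rcpp;

static inline double dnorm_one(double x, double mu, double sd) {
  const double z = (x - mu) / sd;
  return std::exp(-0.5 * z * z) / (sd * std::sqrt(2.0 * M_PI));
}

// Scaled forward-backward pass for one trace under a Gaussian-emission HMM.
// Returns the per-frame posteriors (gamma), the summed pairwise posteriors
// (xi, K x K), the posterior at frame 1, and the log-likelihood.
// [[Rcpp::export(name = ".fb_gaussian")]]
List fb_gaussian(NumericVector x, NumericVector mu, NumericVector sigma,
                 NumericMatrix A, NumericVector pi0) {
  const int T = x.size(), K = mu.size();
  NumericMatrix B(T, K), alpha(T, K), beta(T, K), gamma(T, K);
  NumericMatrix xi(K, K);
  NumericVector c(T);
  const double floor_b = 1e-300;

  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k)
      B(t, k) = std::max(dnorm_one(x[t], mu[k], sigma[k]), floor_b);

  // forward with scaling
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi0[k] * B(0, k); s += alpha(0, k); }
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
      alpha(t, k) = a * B(t, k);
      s += alpha(t, k);
    }
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }

  // backward with the same scaling constants
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      double b = 0.0;
      for (int k = 0; k < K; ++k) b += A(j, k) * B(t + 1, k) * beta(t + 1, k);
      beta(t, j) = b / c[t + 1];
    }
  }

  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }

  for (int t = 0; t < T - 1; ++t) {
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi(j, k) += alpha(t, j) * A(j, k) * B(t + 1, k) * beta(t + 1, k) / c[t + 1];
  }

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(c[t]);

  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["loglik"] = ll, _["gamma1"] = gamma(0, _));
}

// Viterbi decoding (log domain); returns the 1-based most probable path.
// [[Rcpp::export(name = ".viterbi_gaussian")]]
IntegerVector viterbi_gaussian(NumericVector x, NumericVector mu,
                               NumericVector sigma, NumericMatrix A,
                               NumericVector pi0) {
  const int T = x.size(), K = mu.size();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  const double neg_inf = -std::numeric_limits<double>::infinity();

  NumericMatrix logA(K, K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k)
      logA(j, k) = A(j, k) > 0 ? std::log(A(j, k)) : neg_inf;

  for (int k = 0; k < K; ++k)
    delta(0, k) = (pi0[k] > 0 ? std::log(pi0[k]) : neg_inf) +
      std::log(std::max(dnorm_one(x[0], mu[k], sigma[k]), 1e-300));

  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = neg_inf; int arg = 0;
      for (int j = 0; j < K; ++j) {
        const double v = delta(t - 1, j) + logA(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best +
        std::log(std::max(dnorm_one(x[t], mu[k], sigma[k]), 1e-300));
      psi(t, k) = arg;
    }
  }

  IntegerVector path(T);
  int arg = 0; double best = neg_inf;
  for (int k = 0; k < K; ++k) if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
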