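#include <Rcpp.h>
using namespace Rcpp;

// Gaussian-emission HMM primitives on a single observation sequence.
// Scaled forward/backward recursions (Rabiner-style normalization) keep the
// arithmetic in ordinary double range; log-likelihood accumulates the log
// scale factors.

static inline double dnorm_val(double x, double mu, double sigma) {
  double z = (x - mu) / sigma;
  return std::exp(-0.5 * z * z) / (sigma * std::sqrt(2.0 * M_PI));
}

// Emission probability matrix B[t, k], floored at a tiny positive value so a
// single outlying observation cannot zero out an entire forward recursion.
static NumericMatrix emission_matrix(const NumericVector& x,
                                     const NumericVector& mu,
                                     const NumericVector& sigma) {
  const int T = x.size(), K = mu.size();
  NumericMatrix B(T, K);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double p = dnorm_val(x[t], mu[k], sigma[k]);
      B(t, k) = (p > 1e-300) ? p : 1e-300;
    }
  return B;
}

// [[Rcpp::export]]
double hmm_forward_loglik(NumericVector x, NumericVector mu, NumericVector sigma,
                          NumericMatrix A, NumericVector pi) {
  const int T = x.size(), K = mu.size();
  if (T == 0) stop("empty sequence");
  NumericMatrix B = emission_matrix(x, mu, sigma);
  std::vector<double> alpha(K), alpha_new(K);
  double loglik = 0.0;
  double c = 0.0;
  for (int k = 0; k < K; ++k) { alpha[k] = pi[k] * B(0, k); c += alpha[k]; }
  loglik += std::log(c);
  for (int k = 0; k < K; ++k) alpha[k] /= c;
  for (int t = 1; t < T; ++t) {
    c = 0.0;
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += alpha[j] * A(j, k);
      alpha_new[k] = s * B(t, k);
      c += alpha_new[k];
    }
    loglik += std::log(c);
    for (int k = 0; k < K; ++k) alpha[k] = alpha_new[k] / c;
  }
  return loglik;
}

// Forward-backward E-step: returns log-likelihood, state posteriors gamma
// (T x K), summed transition posteriors xi_sum (K x K) and gamma at t = 0.
// [[Rcpp::export]]
List hmm_estep(NumericVector x, NumericVector mu, NumericVector sigma,
               NumericMatrix A, NumericVector pi) {
  const int T = x.size(), K = mu.size();
  if (T == 0) stop("empty sequence");
  NumericMatrix B = emission_matrix(x, mu, sigma);
  NumericMatrix alpha(T, K), beta(T, K);
  NumericVector cvec(T);
  double loglik = 0.0;

  double c = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * B(0, k); c += alpha(0, k); }
  cvec[0] = c; loglik += std::log(c);
  for (int k = 0; k < K; ++k) alpha(0, k) /= c;
  for (int t = 1; t < T; ++t) {
    c = 0.0;
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += alpha(t - 1, j) * A(j, k);
      alpha(t, k) = s * B(t, k);
      c += alpha(t, k);
    }
    cvec[t] = c; loglik += std::log(c);
    for (int k = 0; k < K; ++k) alpha(t, k) /= c;
  }

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t)
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += A(k, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, k) = s / cvec[t + 1];
    }

  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    double norm = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); norm += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= norm;
  }

  NumericMatrix xi_sum(K, K);
  for (int t = 0; t < T - 1; ++t)
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi_sum(j, k) += alpha(t, j) * A(j, k) * B(t + 1, k) * beta(t + 1, k) /
                        cvec[t + 1];

  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xi_sum"] = xi_sum);
}

// E-step reduced to the sufficient statistics the M-step needs, accumulated
// over a list of sequences in one call: total log-likelihood, per-state
// posterior sums (gamma_sum, gamma * x, gamma * x^2), summed transition
// posteriors and summed t = 0 posteriors. Avoids materializing T x K
// posterior matrices for long tracks.
// [[Rcpp::export]]
List hmm_estep_stats(List sequences, NumericVector mu, NumericVector sigma,
                     NumericMatrix A, NumericVector pi) {
  const int K = mu.size();
  const int S = sequences.size();
  double loglik = 0.0;
  NumericVector gamma_sum(K), gx(K), gxx(K), gamma1(K);
  NumericMatrix xi_sum(K, K);
  std::vector<double> Aflat(K * K), logconst(K), inv2s2(K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k) Aflat[j * K + k] = A(j, k);

  for (int si = 0; si < S; ++si) {
    NumericVector x = sequences[si];
    const int T = x.size();
    if (T == 0) stop("empty sequence");
    std::vector<double> B(static_cast<size_t>(T) * K);
    for (int t = 0; t < T; ++t)
      for (int k = 0; k < K; ++k) {
        double p = dnorm_val(x[t], mu[k], sigma[k]);
        B[static_cast<size_t>(t) * K + k] = (p > 1e-300) ? p : 1e-300;
      }
    std::vector<double> alpha(static_cast<size_t>(T) * K),
        beta(static_cast<size_t>(T) * K), cvec(T);
    double c = 0.0;
    for (int k = 0; k < K; ++k) { alpha[k] = pi[k] * B[k]; c += alpha[k]; }
    cvec[0] = c; loglik += std::log(c);
    for (int k = 0; k < K; ++k) alpha[k] /= c;
    for (int t = 1; t < T; ++t) {
      double* at = &alpha[static_cast<size_t>(t) * K];
      const double* ap = &alpha[static_cast<size_t>(t - 1) * K];
      const double* bt = &B[static_cast<size_t>(t) * K];
      c = 0.0;
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int j = 0; j < K; ++j) s += ap[j] * Aflat[j * K + k];
        at[k] = s * bt[k];
        c += at[k];
      }
      cvec[t] = c; loglik += std::log(c);
      for (int k = 0; k < K; ++k) at[k] /= c;
    }
    for (int k = 0; k < K; ++k) beta[static_cast<size_t>(T - 1) * K + k] = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      double* bt_ = &beta[static_cast<size_t>(t) * K];
      const double* bn = &beta[static_cast<size_t>(t + 1) * K];
      const double* Bn = &B[static_cast<size_t>(t + 1) * K];
      const double invc = 1.0 / cvec[t + 1];
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int j = 0; j < K; ++j) s += Aflat[k * K + j] * Bn[j] * bn[j];
        bt_[k] = s * invc;
      }
    }
    for (int t = 0; t < T; ++t) {
      const double* at = &alpha[static_cast<size_t>(t) * K];
      const double* bt_ = &beta[static_cast<size_t>(t) * K];
      double norm = 0.0;
      for (int k = 0; k < K; ++k) norm += at[k] * bt_[k];
      const double xt = x[t];
      for (int k = 0; k < K; ++k) {
        double g = at[k] * bt_[k] / norm;
        gamma_sum[k] += g; gx[k] += g * xt; gxx[k] += g * xt * xt;
        if (t == 0) gamma1[k] += g;
      }
    }
    for (int t = 0; t < T - 1; ++t) {
      const double* at = &alpha[static_cast<size_t>(t) * K];
      const double* bn = &beta[static_cast<size_t>(t + 1) * K];
      const double* Bn = &B[static_cast<size_t>(t + 1) * K];
      const double invc = 1.0 / cvec[t + 1];
      for (int j = 0; j < K; ++j)
        for (int k = 0; k < K; ++k)
          xi_sum(j, k) += at[j] * Aflat[j * K + k] * Bn[k] * bn[k] * invc;
    }
  }
  return List::create(_["loglik"] = loglik, _["gamma_sum"] = gamma_sum,
                      _["gx"] = gx, _["gxx"] = gxx, _["xi_sum"] = xi_sum,
                      _["gamma1"] = gamma1);
}

// Viterbi decoding in log space. Ties in path score are broken toward the
// lower state index (strict > comparison), making decoding deterministic.
// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericVector x, NumericVector mu, NumericVector sigma,
                          NumericMatrix A, NumericVector pi) {
  const int T = x.size(), K = mu.size();
  if (T == 0) stop("empty sequence");
  NumericMatrix logB(T, K), logA(K, K);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double z = (x[t] - mu[k]) / sigma[k];
      logB(t, k) = -0.5 * z * z - std::log(sigma[k]) - 0.5 * std::log(2.0 * M_PI);
    }
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k)
      logA(j, k) = (A(j, k) > 0) ? std::log(A(j, k)) : -1e300;

  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k)
    delta(0, k) = ((pi[k] > 0) ? std::log(pi[k]) : -1e300) + logB(0, k);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      int best_j = 0;
      double best = delta(t - 1, 0) + logA(0, k);
      for (int j = 1; j < K; ++j) {
        double v = delta(t - 1, j) + logA(j, k);
        if (v > best) { best = v; best_j = j; }
      }
      delta(t, k) = best + logB(t, k);
      psi(t, k) = best_j;
    }

  IntegerVector path(T);
  int best_k = 0;
  double best = delta(T - 1, 0);
  for (int k = 1; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); best_k = k; }
  path[T - 1] = best_k;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1;  // 1-based state indices for R
  return path;
}
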