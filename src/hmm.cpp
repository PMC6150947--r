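#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// log-sum-exp over a row segment
static inline double lse(const double* x, int n) {
  double m = x[0];
  for (int i = 1; i < n; ++i) if (x[i] > m) m = x[i];
  if (!std::isfinite(m)) return m;
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::exp(x[i] - m);
  return m + std::log(s);
}

// Scaled forward-backward for a discrete-state HMM with precomputed
// per-sample log observation densities (T x K). Returns the data
// log-likelihood, posterior state probabilities gamma (T x K) and the
// summed two-slice transition counts xi (K x K).
// [[Rcpp::export]]
List hmm_forward_backward(NumericMatrix logdens, NumericVector log_pi,
                          NumericMatrix log_A) {
  const int T = logdens.nrow(), K = logdens.ncol();
  NumericMatrix la(T, K);   // log alpha
  NumericMatrix lb(T, K);   // log beta
  std::vector<double> buf(K);

  for (int k = 0; k < K; ++k) la(0, k) = log_pi[k] + logdens(0, k);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j) buf[j] = la(t - 1, j) + log_A(j, k);
      la(t, k) = lse(buf.data(), K) + logdens(t, k);
    }
  double loglik;
  {
    std::vector<double> last(K);
    for (int k = 0; k < K; ++k) last[k] = la(T - 1, k);
    loglik = lse(last.data(), K);
  }
  for (int k = 0; k < K; ++k) lb(T - 1, k) = 0.0;
  for (int t = T - 2; t >= 0; --t)
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j)
        buf[j] = log_A(k, j) + logdens(t + 1, j) + lb(t + 1, j);
      lb(t, k) = lse(buf.data(), K);
    }

  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k)
      gamma(t, k) = std::exp(la(t, k) + lb(t, k) - loglik);

  NumericMatrix xi(K, K);
  for (int t = 0; t + 1 < T; ++t)
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi(j, k) += std::exp(la(t, j) + log_A(j, k) + logdens(t + 1, k) +
                             lb(t + 1, k) - loglik);

  return List::create(_["loglik"] = loglik, _["gamma"] = gamma, _["xi"] = xi);
}

// Viterbi decoding; returns the 1-based most probable state path.
// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericMatrix logdens, NumericVector log_pi,
                          NumericMatrix log_A) {
  const int T = logdens.nrow(), K = logdens.ncol();
  NumericMatrix d(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) d(0, k) = log_pi[k] + logdens(0, k);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double best = d(t - 1, 0) + log_A(0, k);
      int arg = 0;
      for (int j = 1; j < K; ++j) {
        double v = d(t - 1, j) + log_A(j, k);
        if (v > best) { best = v; arg = j; }
      }
      d(t, k) = best + logdens(t, k);
      psi(t, k) = arg;
    }
  IntegerVector path(T);
  int arg = 0;
  for (int k = 1; k < K; ++k) if (d(T - 1, k) > d(T - 1, arg)) arg = k;
  path[T - 1] = arg + 1;
  for (int t = T - 1; t > 0; --t) {
    arg = psi(t, arg);
    path[t - 1] = arg + 1;
  }
  return path;
}
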