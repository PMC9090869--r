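#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-state Gaussian HMM recursions with per-step scaling.
// Emission log-densities are max-shifted per minute before exponentiation so
// a single outlying value cannot underflow both states simultaneously
// (contract: stable for series of length 10080 = 7 x 1440 minutes).

static inline double ldnorm(double y, double mu, double sd) {
  double z = (y - mu) / sd;
  return -0.5 * z * z - std::log(sd) - 0.9189385332046727; // log(sqrt(2*pi))
}

// scaled emission probabilities at minute t, returns the shift used
static inline double emis(double y, const NumericVector &mu,
                          const NumericVector &sd, double *b) {
  double l0 = ldnorm(y, mu[0], sd[0]);
  double l1 = ldnorm(y, mu[1], sd[1]);
  double m = l0 > l1 ? l0 : l1;
  b[0] = std::exp(l0 - m);
  b[1] = std::exp(l1 - m);
  return m;
}

// [[Rcpp::export(name = ".hmm_forward_cpp")]]
double hmm_forward_cpp(NumericVector y, NumericVector pi, NumericMatrix A,
                       NumericVector mu, NumericVector sd) {
  int T = y.size();
  double b[2], a0, a1, ll = 0.0;
  double m = emis(y[0], mu, sd, b);
  a0 = pi[0] * b[0];
  a1 = pi[1] * b[1];
  double c = a0 + a1;
  ll += std::log(c) + m;
  a0 /= c; a1 /= c;
  for (int t = 1; t < T; ++t) {
    m = emis(y[t], mu, sd, b);
    double n0 = (a0 * A(0, 0) + a1 * A(1, 0)) * b[0];
    double n1 = (a0 * A(0, 1) + a1 * A(1, 1)) * b[1];
    c = n0 + n1;
    ll += std::log(c) + m;
    a0 = n0 / c; a1 = n1 / c;
  }
  return ll;
}

// forward-backward: posterior state probabilities and expected transition
// counts, as consumed by one Baum-Welch M-step
// [[Rcpp::export(name = ".hmm_fb_cpp")]]
List hmm_fb_cpp(NumericVector y, NumericVector pi, NumericMatrix A,
                NumericVector mu, NumericVector sd) {
  int T = y.size();
  NumericMatrix alpha(T, 2), beta(T, 2), gamma(T, 2), bmat(T, 2);
  NumericVector cvec(T);
  double b[2], ll = 0.0;

  double m = emis(y[0], mu, sd, b);
  bmat(0, 0) = b[0]; bmat(0, 1) = b[1];
  alpha(0, 0) = pi[0] * b[0];
  alpha(0, 1) = pi[1] * b[1];
  double c = alpha(0, 0) + alpha(0, 1);
  cvec[0] = c;
  ll += std::log(c) + m;
  alpha(0, 0) /= c; alpha(0, 1) /= c;
  for (int t = 1; t < T; ++t) {
    m = emis(y[t], mu, sd, b);
    bmat(t, 0) = b[0]; bmat(t, 1) = b[1];
    double n0 = (alpha(t - 1, 0) * A(0, 0) + alpha(t - 1, 1) * A(1, 0)) * b[0];
    double n1 = (alpha(t - 1, 0) * A(0, 1) + alpha(t - 1, 1) * A(1, 1)) * b[1];
    c = n0 + n1;
    cvec[t] = c;
    ll += std::log(c) + m;
    alpha(t, 0) = n0 / c; alpha(t, 1) = n1 / c;
  }

  beta(T - 1, 0) = 1.0; beta(T - 1, 1) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    double b0 = bmat(t + 1, 0) * beta(t + 1, 0);
    double b1 = bmat(t + 1, 1) * beta(t + 1, 1);
    beta(t, 0) = (A(0, 0) * b0 + A(0, 1) * b1) / cvec[t + 1];
    beta(t, 1) = (A(1, 0) * b0 + A(1, 1) * b1) / cvec[t + 1];
  }

  for (int t = 0; t < T; ++t) {
    double g0 = alpha(t, 0) * beta(t, 0);
    double g1 = alpha(t, 1) * beta(t, 1);
    double s = g0 + g1;
    gamma(t, 0) = g0 / s; gamma(t, 1) = g1 / s;
  }

  NumericMatrix xi(2, 2);
  for (int t = 0; t < T - 1; ++t) {
    double denom = cvec[t + 1];
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j)
        xi(i, j) += alpha(t, i) * A(i, j) * bmat(t + 1, j) *
                    beta(t + 1, j) / denom;
  }

  return List::create(Named("gamma") = gamma, Named("xi") = xi,
                      Named("loglik") = ll);
}

// [[Rcpp::export(name = ".hmm_viterbi_cpp")]]
IntegerVector hmm_viterbi_cpp(NumericVector y, NumericVector pi,
                              NumericMatrix A, NumericVector mu,
                              NumericVector sd) {
  int T = y.size();
  NumericMatrix delta(T, 2);
  IntegerMatrix psi(T, 2);
  double lA[2][2];
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j)
      lA[i][j] = std::log(A(i, j));
  delta(0, 0) = std::log(pi[0]) + ldnorm(y[0], mu[0], sd[0]);
  delta(0, 1) = std::log(pi[1]) + ldnorm(y[0], mu[1], sd[1]);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < 2; ++j) {
      double v0 = delta(t - 1, 0) + lA[0][j];
      double v1 = delta(t - 1, 1) + lA[1][j];
      if (v0 >= v1) { delta(t, j) = v0; psi(t, j) = 0; }
      else          { delta(t, j) = v1; psi(t, j) = 1; }
      delta(t, j) += ldnorm(y[t], mu[j], sd[j]);
    }
  }
  IntegerVector path(T);
  path[T - 1] = delta(T - 1, 0) >= delta(T - 1, 1) ? 0 : 1;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path;
}
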