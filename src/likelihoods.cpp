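// Vectorized log-likelihood kernels evaluated across many parameter draws.
// These mirror the scalar R implementations in R/likelihood.R; the R and
// C++ routes are cross-checked in the test suite.

#include <Rcpp.h>
using namespace Rcpp;

static const double LN_SQRT_2PI = 0.918938533204672742;

// random-effects: sum_i log phi(z_i; mu_n, sqrt(tau_n^2 + se_i^2))
// [[Rcpp::export]]
NumericVector ll_re_cpp(NumericVector z, NumericVector se,
                        NumericVector mu, NumericVector tau) {
  const int K = z.size(), N = mu.size();
  NumericVector out(N);
  for (int n = 0; n < N; ++n) {
    double acc = 0.0, t2 = tau[n] * tau[n];
    for (int i = 0; i < K; ++i) {
      double s2 = t2 + se[i] * se[i];
      double r = z[i] - mu[n];
      acc += -LN_SQRT_2PI - 0.5 * std::log(s2) - 0.5 * r * r / s2;
    }
    out[n] = acc;
  }
  return out;
}

// PET (order 1) / PEESE (order 2) meta-regression
// [[Rcpp::export]]
NumericVector ll_petpeese_cpp(NumericVector z, NumericVector se,
                              NumericVector mu, NumericVector tau,
                              NumericVector coef, int order) {
  const int K = z.size(), N = mu.size();
  NumericVector out(N);
  std::vector<double> sek(K);
  for (int i = 0; i < K; ++i)
    sek[i] = (order == 1) ? se[i] : se[i] * se[i];
  for (int n = 0; n < N; ++n) {
    double acc = 0.0, t2 = tau[n] * tau[n];
    for (int i = 0; i < K; ++i) {
      double s2 = t2 + se[i] * se[i];
      double r = z[i] - mu[n] - coef[n] * sek[i];
      acc += -LN_SQRT_2PI - 0.5 * std::log(s2) - 0.5 * r * r / s2;
    }
    out[n] = acc;
  }
  return out;
}

// Selection-model weighted likelihood.
// cut_q: qnorm-transformed p-value cut-offs (length J-1, decreasing in
// significance); omega: N x J weights; idx: interval of each study's
// observed p-value (1-based). For one-sided weighting the study-level
// thresholds on z are se_i * cut_q[j]; for two-sided they are +/- the same
// with the absolute value folded in.
// [[Rcpp::export]]
NumericVector ll_sel_cpp(NumericVector z, NumericVector se,
                         NumericVector mu, NumericVector tau,
                         NumericMatrix omega, NumericVector cut_q,
                         IntegerVector idx, bool one_sided) {
  const int K = z.size(), N = mu.size(), J = omega.ncol();
  NumericVector out(N);
  for (int n = 0; n < N; ++n) {
    double acc = 0.0, t2 = tau[n] * tau[n];
    for (int i = 0; i < K; ++i) {
      double s2 = t2 + se[i] * se[i];
      double s = std::sqrt(s2);
      double r = z[i] - mu[n];
      double dens = -LN_SQRT_2PI - std::log(s) - 0.5 * r * r / s2;
      double A = 0.0;
      if (one_sided) {
        double upper = 1.0;  // Phi(+inf)
        for (int j = 0; j < J; ++j) {
          double lower = (j == J - 1)
            ? 0.0
            : R::pnorm(se[i] * cut_q[j], mu[n], s, 1, 0);
          A += omega(n, j) * (upper - lower);
          upper = lower;
        }
      } else {
        double up_pos = 1.0, up_neg = 0.0;
        for (int j = 0; j < J; ++j) {
          double lo_pos, lo_neg;
          if (j == J - 1) {
            lo_pos = lo_neg = R::pnorm(0.0, mu[n], s, 1, 0);
          } else {
            double b = se[i] * cut_q[j];
            lo_pos = R::pnorm(b, mu[n], s, 1, 0);
            lo_neg = R::pnorm(-b, mu[n], s, 1, 0);
          }
          double pr = (up_pos - lo_pos) + (lo_neg - up_neg);
          if (pr < 0) pr = 0;
          A += omega(n, j) * pr;
          up_pos = lo_pos;
          up_neg = lo_neg;
        }
      }
      acc += std::log(omega(n, idx[i] - 1)) + dens - std::log(A);
    }
    out[n] = acc;
  }
  return out;
}
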