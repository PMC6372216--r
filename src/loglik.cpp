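#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

inline double log_sum_exp2(double x, double y) {
  double m = x > y ? x : y;
  return m + std::log(std::exp(x - m) + std::exp(y - m));
}

}  // namespace

// Forward response log-likelihood of the explicit-duration HMM agent,
// conditioned on the observed sequence of choices and outcomes.
//
// choice:  0 = A, 1 = B (observed responses)
// outcome: -1 or +1 (observed feedback)
// pmf:     duration prior over d = 1..d_max (normalized)
// The log probabilities of the observed choices are accumulated for trials
// t_from..t_to (1-based); beliefs are propagated over all trials up to t_to.
// [[Rcpp::export]]
double edhmm_loglik_cpp(IntegerVector choice, NumericVector outcome,
                        NumericVector pmf, double a0A, double b0A,
                        double a0B, double b0B, double theta0, double beta,
                        double bias, int t_from, int t_to) {
  const int T = choice.size();
  if (outcome.size() != T) stop("choice/outcome length mismatch");
  if (t_to > T || t_from < 1 || t_from > t_to) stop("invalid trial range");
  const int dm = pmf.size();

  std::vector<double> nr_buf(dm), rr_buf(dm), nn_buf(dm), nrw_buf(dm);
  double *nr = nr_buf.data(), *rr = rr_buf.data();
  double *nn = nn_buf.data(), *nrw = nrw_buf.data();
  for (int i = 0; i < dm; ++i) {
    nr[i] = theta0 * pmf[i];
    rr[i] = (1.0 - theta0) * pmf[i];
  }
  double thetaT = theta0;  // maintained incrementally: sum of the NR row
  double a[2] = {a0A, a0B};
  double b[2] = {b0A, b0B};
  const double logbias[2] = {std::log(bias), std::log(1.0 - bias)};
  double ll = 0.0;

  for (int t = 0; t < t_to; ++t) {
    const double muA = a[0] / (a[0] + b[0]);
    const double muB = a[1] / (a[1] + b[1]);
    const double VA = 2.0 * muA - 1.0;
    const double VB = 2.0 * muB - 1.0;
    const double VtA = thetaT * VA + (1.0 - thetaT) * VB;
    const double VtB = thetaT * VB + (1.0 - thetaT) * VA;

    const int c = choice[t];
    if (c != 0 && c != 1) stop("choices must be coded 0 (A) or 1 (B)");
    if (t + 1 >= t_from) {
      const double lA = beta * VtA + logbias[0];
      const double lB = beta * VtB + logbias[1];
      ll += (c == 0 ? lA : lB) - log_sum_exp2(lA, lB);
    }

    // state update from the observed outcome
    const double obar = (outcome[t] + 1.0) / 2.0;
    const double mu_c = (c == 0) ? muA : muB;
    const double mu_o = (c == 0) ? muB : muA;
    const double lNR = obar * mu_c + (1.0 - obar) * (1.0 - mu_c);
    const double lR = obar * mu_o + (1.0 - obar) * (1.0 - mu_o);
    const double denom = thetaT * lNR + (1.0 - thetaT) * lR;
    const double theta = thetaT * lNR / denom;
    const double wNR = thetaT > 0.0 ? theta / thetaT : 0.0;
    const double wR = thetaT < 1.0 ? (1.0 - theta) / (1.0 - thetaT) : 0.0;

    // state-weighted Beta-Bernoulli reward update
    const int o = 1 - c;
    a[c] += theta * obar;
    b[c] += theta * (1.0 - obar);
    a[o] += (1.0 - theta) * obar;
    b[o] += (1.0 - theta) * (1.0 - obar);

    // row rescale (posterior) fused with the semi-Markov propagation:
    // countdown, flip on exhausted counter; total mass is conserved
    const double flip_nr = wR * rr[0];
    const double flip_rr = wNR * nr[0];
    for (int i = 0; i + 1 < dm; ++i) {
      nn[i] = wNR * nr[i + 1] + pmf[i] * flip_nr;
      nrw[i] = wR * rr[i + 1] + pmf[i] * flip_rr;
    }
    nn[dm - 1] = pmf[dm - 1] * flip_nr;
    nrw[dm - 1] = pmf[dm - 1] * flip_rr;
    std::swap(nr, nn);
    std::swap(rr, nrw);
    thetaT = theta - flip_rr + flip_nr;
  }
  return ll;
}

// Forward response log-likelihood of the (dual-update) Rescorla-Wagner
// agent; kappa = 0 reduces to the single-update rule.
// [[Rcpp::export]]
double rw_loglik_cpp(IntegerVector choice, NumericVector outcome,
                     double alpha, double kappa, double V0A, double V0B,
                     double beta, double bias, int t_from, int t_to) {
  const int T = choice.size();
  if (outcome.size() != T) stop("choice/outcome length mismatch");
  if (t_to > T || t_from < 1 || t_from > t_to) stop("invalid trial range");
  double V[2] = {V0A, V0B};
  const double logbias[2] = {std::log(bias), std::log(1.0 - bias)};
  double ll = 0.0;
  for (int t = 0; t < t_to; ++t) {
    const int c = choice[t];
    if (c != 0 && c != 1) stop("choices must be coded 0 (A) or 1 (B)");
    if (t + 1 >= t_from) {
      const double lA = beta * V[0] + logbias[0];
      const double lB = beta * V[1] + logbias[1];
      ll += (c == 0 ? lA : lB) - log_sum_exp2(lA, lB);
    }
    const int o = 1 - c;
    V[c] += alpha * (outcome[t] - V[c]);
    V[o] += kappa * alpha * (-outcome[t] - V[o]);
  }
  return ll;
}
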