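#include <Rcpp.h>
using namespace Rcpp;

// Trial-by-trial negative log-likelihood of a two-step session under the
// hybrid model family. Parameter layout in `par` by `variant`:
//   0 hybrid:          alpha, beta, pi, omega
//   1 dual_rate:       alpha_pos, alpha_neg, beta, pi, omega
//   2 separate_values: alpha_mf, alpha_mb, beta, pi, omega
//   3 actor_critic:    alpha, eta, beta, pi, omega
// mapping0 is the second-stage state commonly reached by action 0 (action 1
// maps to the other state). Mirrors the R reference path exactly.

static inline double log_softmax_chosen(double x0, double x1, int chosen) {
  double m = x0 > x1 ? x0 : x1;
  double lse = m + std::log(std::exp(x0 - m) + std::exp(x1 - m));
  return (chosen == 0 ? x0 : x1) - lse;
}

// [[Rcpp::export]]
double twostep_nll_cpp(NumericVector par, IntegerVector choice1,
                       IntegerVector state2, IntegerVector choice2,
                       IntegerVector reward, int variant, double common_prob,
                       double lambda, int mapping0) {
  int n = choice1.size();
  double q1[2] = {0, 0};
  double q2[2][2] = {{0, 0}, {0, 0}};
  double q2mb[2][2] = {{0, 0}, {0, 0}};
  double v[3] = {0, 0, 0};
  double prefs1[2] = {0, 0};
  double prefs2[2][2] = {{0, 0}, {0, 0}};
  int prev = -1;

  double alpha = 0, beta, ppi, omega;
  double a_pos = 0, a_neg = 0, a_mf = 0, a_mb = 0, eta = 0;
  if (variant == 0) {
    alpha = par[0]; beta = par[1]; ppi = par[2]; omega = par[3];
  } else if (variant == 1) {
    a_pos = par[0]; a_neg = par[1]; beta = par[2]; ppi = par[3];
    omega = par[4];
  } else if (variant == 2) {
    a_mf = par[0]; a_mb = par[1]; beta = par[2]; ppi = par[3];
    omega = par[4];
  } else if (variant == 3) {
    alpha = par[0]; eta = par[1]; beta = par[2]; ppi = par[3];
    omega = par[4];
  } else {
    stop("unknown variant code");
  }

  int map[2] = {mapping0, 1 - mapping0};
  double ll = 0.0;

  for (int t = 0; t < n; t++) {
    int c1 = choice1[t], s2 = state2[t], c2 = choice2[t];
    double r = reward[t];

    // model-based first-stage values from the relevant second-stage table
    double best[2];
    if (variant == 2) {
      best[0] = q2mb[0][0] > q2mb[0][1] ? q2mb[0][0] : q2mb[0][1];
      best[1] = q2mb[1][0] > q2mb[1][1] ? q2mb[1][0] : q2mb[1][1];
    } else {
      best[0] = q2[0][0] > q2[0][1] ? q2[0][0] : q2[0][1];
      best[1] = q2[1][0] > q2[1][1] ? q2[1][0] : q2[1][1];
    }
    double net[2];
    for (int a = 0; a < 2; a++) {
      double qmb = common_prob * best[map[a]] +
                   (1.0 - common_prob) * best[1 - map[a]];
      double qmf = (variant == 3) ? prefs1[a] : q1[a];
      net[a] = omega * qmb + (1.0 - omega) * qmf;
    }
    double x0 = beta * net[0] + (prev == 0 ? ppi : 0.0);
    double x1 = beta * net[1] + (prev == 1 ? ppi : 0.0);
    ll += log_softmax_chosen(x0, x1, c1);

    // second-stage choice
    double r0, r1;
    if (variant == 3) {
      r0 = prefs2[s2][0]; r1 = prefs2[s2][1];
    } else {
      r0 = q2[s2][0]; r1 = q2[s2][1];
    }
    ll += log_softmax_chosen(beta * r0, beta * r1, c2);

    // learning
    if (variant == 0) {
      double d1 = q2[s2][c2] - q1[c1];
      q1[c1] += alpha * d1;
      double d2 = r - q2[s2][c2];
      q2[s2][c2] += alpha * d2;
      q1[c1] += lambda * alpha * d2;
    } else if (variant == 1) {
      double d1 = q2[s2][c2] - q1[c1];
      double rt1 = d1 > 0 ? a_pos : a_neg;
      q1[c1] += rt1 * d1;
      double d2 = r - q2[s2][c2];
      double rt2 = d2 > 0 ? a_pos : a_neg;
      q2[s2][c2] += rt2 * d2;
      q1[c1] += lambda * rt2 * d2;
    } else if (variant == 2) {
      double d1 = q2[s2][c2] - q1[c1];
      q1[c1] += a_mf * d1;
      double d2 = r - q2[s2][c2];
      q2[s2][c2] += a_mf * d2;
      q1[c1] += lambda * a_mf * d2;
      double dmb = r - q2mb[s2][c2];
      q2mb[s2][c2] += a_mb * dmb;
    } else {
      double d1 = v[1 + s2] - v[0];
      v[0] += alpha * d1;
      prefs1[c1] += eta * d1;
      double d2 = r - v[1 + s2];
      v[1 + s2] += alpha * d2;
      prefs2[s2][c2] += eta * d2;
      double dq = r - q2[s2][c2];
      q2[s2][c2] += alpha * dq;
    }
    prev = c1;
  }

  double nll = -ll;
  if (!R_finite(nll)) return R_PosInf;
  return nll;
}
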