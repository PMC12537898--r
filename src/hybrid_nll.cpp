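#include <Rcpp.h>
using namespace Rcpp;

// Negative log-likelihood of a single-subject two-step trial sequence under
// the hybrid model-free/model-based learner. Mirrors the R-level
// update_values() recursion; kept in compiled code because per-subject MAP
// fitting evaluates it tens of thousands of times.
//
// a1, s2, a2: 0/1 codes; r: delivered points. Values initialised at 0.
// [[Rcpp::export]]
double hybrid_nll_cpp(IntegerVector a1, IntegerVector s2, IntegerVector a2,
                      NumericVector r,
                      double alpha1, double alpha2, double lam,
                      double beta1, double beta2, double omega,
                      double rep_bonus, double p_common) {
  const int n = a1.size();
  double qmf[2] = {0.0, 0.0};
  double q2[2][2] = {{0.0, 0.0}, {0.0, 0.0}};
  double nll = 0.0;
  int prev = -1;

  for (int t = 0; t < n; ++t) {
    // model-based stage-1 values through the transition model
    double best0 = q2[0][0] > q2[0][1] ? q2[0][0] : q2[0][1];
    double best1 = q2[1][0] > q2[1][1] ? q2[1][0] : q2[1][1];
    double qmb0 = p_common * best0 + (1.0 - p_common) * best1;
    double qmb1 = p_common * best1 + (1.0 - p_common) * best0;
    double x0 = beta1 * (omega * qmb0 + (1.0 - omega) * qmf[0]);
    double x1 = beta1 * (omega * qmb1 + (1.0 - omega) * qmf[1]);
    if (prev == 0) x0 += rep_bonus;
    if (prev == 1) x1 += rep_bonus;
    double m = x0 > x1 ? x0 : x1;
    double lse = m + std::log(std::exp(x0 - m) + std::exp(x1 - m));
    nll -= (a1[t] == 0 ? x0 : x1) - lse;

    const int s = s2[t];
    double y0 = beta2 * q2[s][0];
    double y1 = beta2 * q2[s][1];
    m = y0 > y1 ? y0 : y1;
    lse = m + std::log(std::exp(y0 - m) + std::exp(y1 - m));
    nll -= (a2[t] == 0 ? y0 : y1) - lse;

    // SARSA(lambda)-style updates
    const int c1 = a1[t], c2 = a2[t];
    double delta1 = q2[s][c2] - qmf[c1];
    qmf[c1] += alpha1 * delta1;
    double delta2 = r[t] - q2[s][c2];
    q2[s][c2] += alpha2 * delta2;
    qmf[c1] += alpha1 * lam * delta2;
    prev = c1;
  }
  return nll;
}
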