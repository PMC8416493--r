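#include <Rcpp.h>
using namespace Rcpp;

// Forward-rollout log-likelihood of a door-choice sequence under the
// Value-Plus-Perseveration model.  choice is 1-based door index (A=1..D=4),
// net the signed net outcome of each trial.  EV and perseveration strengths
// start at zero; the state is updated with the recorded outcome after the
// choice probability is scored.  Softmax sensitivity is theta = 3^c - 1,
// computed with a max shift for numerical stability.
// [[Rcpp::export]]
double vpp_loglik_cpp(IntegerVector choice, NumericVector net,
                      double phi, double alpha, double lambda,
                      double eps_pos, double eps_neg, double k,
                      double w, double c) {
  const int n = choice.size();
  if (net.size() != n) stop("choice and net lengths differ");
  double ev[4] = {0.0, 0.0, 0.0, 0.0};
  double per[4] = {0.0, 0.0, 0.0, 0.0};
  const double theta = std::pow(3.0, c) - 1.0;
  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    const int j = choice[t] - 1;
    if (j < 0 || j > 3) stop("door index out of range at trial %d", t + 1);
    double v[4];
    double vmax = -INFINITY;
    for (int m = 0; m < 4; ++m) {
      v[m] = theta * (w * ev[m] + (1.0 - w) * per[m]);
      if (v[m] > vmax) vmax = v[m];
    }
    double se = 0.0;
    for (int m = 0; m < 4; ++m) se += std::exp(v[m] - vmax);
    ll += v[j] - vmax - std::log(se);
    const double x = net[t];
    const double u = (x >= 0.0) ? std::pow(x, alpha)
                                : -lambda * std::pow(-x, alpha);
    ev[j] += phi * (u - ev[j]);
    for (int m = 0; m < 4; ++m) per[m] *= k;
    per[j] += (x >= 0.0) ? eps_pos : eps_neg;
  }
  return ll;
}
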