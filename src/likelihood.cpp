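#include <Rcpp.h>
using namespace Rcpp;

// Model codes shared with R/models.R:
//   family: 0 = softmax (inverse temperature beta), 1 = rho (reinforcement
//           sensitivity, softmax slope fixed at 1)
//   update: 0 = SU (chosen option only), 1 = DU (mirrored counterfactual
//           update of the unchosen option), 2 = DU with attenuation kappa
//   first_rule (2-beta specs, trial 1 of a session has no previous feedback):
//           0 = use win parameter, 1 = loss parameter, 2 = average
//
// Native parameter layout (canonical order, see enumerate_models()):
//   [choice par(s): beta|rho, or win,loss pair] [alpha, or alpha_win,alpha_loss] [kappa]

static double session_nll(const double *par,
                          const int *choice, const double *reward, int n,
                          int family, int update, int n_lr, int n_ch,
                          int first_rule) {
  int idx = 0;
  const double ch_win  = par[idx++];
  const double ch_loss = (n_ch == 2) ? par[idx++] : ch_win;
  const double a_win   = par[idx++];
  const double a_loss  = (n_lr == 2) ? par[idx++] : a_win;
  const double kappa   = (update == 2) ? par[idx++] : 1.0;

  double q0 = 0.0, q1 = 0.0;   // values reset to 0 at session start
  double nll = 0.0;
  int prev = 0;                // 0 = undefined (first trial), else +1/-1
  const double logfloor = std::log(1e-12);

  for (int t = 0; t < n; ++t) {
    double b = 1.0;
    if (family == 0) {
      if (n_ch == 1)        b = ch_win;
      else if (prev == 1)   b = ch_win;
      else if (prev == -1)  b = ch_loss;
      else                  b = (first_rule == 1) ? ch_loss :
                                (first_rule == 2) ? 0.5 * (ch_win + ch_loss) :
                                ch_win;
    }
    const int c = choice[t];
    double qc = (c == 0) ? q0 : q1;
    double qu = (c == 0) ? q1 : q0;

    // log p(chosen) with the overflow-safe logistic form
    const double z = b * (qc - qu);
    double logp = (z > 0.0) ? -std::log1p(std::exp(-z))
                            : z - std::log1p(std::exp(z));
    if (logp < logfloor) logp = logfloor;
    nll -= logp;

    const double r = reward[t];
    const double a = (n_lr == 1) ? a_win : (r > 0.0 ? a_win : a_loss);
    double rs = r;
    if (family == 1) {
      const double rho = (n_ch == 1) ? ch_win : (r > 0.0 ? ch_win : ch_loss);
      rs = rho * r;
    }
    qc += a * (rs - qc);
    if (update >= 1) {
      const double w = (update == 2) ? kappa : 1.0;
      qu += w * a * ((-rs) - qu);
    }
    if (c == 0) { q0 = qc; q1 = qu; } else { q1 = qc; q0 = qu; }
    prev = (r > 0.0) ? 1 : -1;
  }
  return nll;
}

// [[Rcpp::export]]
double nll_session_cpp(NumericVector par, IntegerVector choice,
                       NumericVector reward,
                       int family, int update, int n_lr, int n_ch,
                       int first_rule) {
  if (choice.size() == 0) return 0.0;
  return session_nll(par.begin(), choice.begin(), reward.begin(),
                     choice.size(), family, update, n_lr, n_ch, first_rule);
}

// Batched evaluation over rows of a native-parameter matrix (used by the
// Monte-Carlo iBIC integration, where thousands of prior draws are scored
// against the same session).
// [[Rcpp::export]]
NumericVector nll_batch_cpp(NumericMatrix par, IntegerVector choice,
                            NumericVector reward,
                            int family, int update, int n_lr, int n_ch,
                            int first_rule) {
  const int K = par.nrow(), d = par.ncol(), n = choice.size();
  NumericVector out(K);
  if (n == 0) return out;
  std::vector<double> row(d);
  for (int k = 0; k < K; ++k) {
    for (int j = 0; j < d; ++j) row[j] = par(k, j);
    out[k] = session_nll(row.data(), choice.begin(), reward.begin(), n,
                         family, update, n_lr, n_ch, first_rule);
  }
  return out;
}
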