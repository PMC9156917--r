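#include <Rcpp.h>
using namespace Rcpp;

// Parameter vector layout used throughout:
// [0] centre (km), [1] width (km), [2] pmin, [3] pmax,
// [4] deltaL (km), [5] deltaR (km), [6] tauL, [7] tauR.
// Inactive parameters are carried at fixed values.

static inline double cline_f(double x, const double *th, bool tails) {
  const double c = th[0], w = th[1];
  double f;
  if (tails && x < c - th[4]) {
    const double dL = th[4], tL = th[6];
    f = (1.0 / (1.0 + std::exp(4.0 * dL / w))) *
        std::exp((4.0 * tL * (x - c + dL) / w) /
                 (1.0 + std::exp(-4.0 * dL / w)));
  } else if (tails && x > c + th[5]) {
    const double dR = th[5], tR = th[7];
    f = 1.0 - (1.0 / (1.0 + std::exp(4.0 * dR / w))) *
        std::exp((-4.0 * tR * (x - c - dR) / w) /
                 (1.0 + std::exp(-4.0 * dR / w)));
  } else {
    f = 1.0 / (1.0 + std::exp(-4.0 * (x - c) / w));
  }
  return f;
}

// [[Rcpp::export(name = ".cline_value_cpp")]]
NumericVector cline_value_cpp(NumericVector x, NumericVector theta,
                              bool tails) {
  const int n = x.size();
  NumericVector out(n);
  const double pmin = theta[2], pmax = theta[3];
  for (int i = 0; i < n; ++i) {
    double f = cline_f(x[i], theta.begin(), tails);
    out[i] = pmin + (pmax - pmin) * f;
  }
  return out;
}

static double loglik(const double *th, bool tails, const NumericVector &x,
                     const NumericVector &q, const NumericVector &m,
                     double eps) {
  double ll = 0.0;
  const double pmin = th[2], pmax = th[3];
  for (int i = 0; i < x.size(); ++i) {
    double p = pmin + (pmax - pmin) * cline_f(x[i], th, tails);
    if (p < eps) p = eps;
    if (p > 1.0 - eps) p = 1.0 - eps;
    ll += m[i] * (q[i] * std::log(p) + (1.0 - q[i]) * std::log(1.0 - p));
  }
  return ll;
}

// [[Rcpp::export(name = ".cline_loglik_cpp")]]
double cline_loglik_cpp(NumericVector theta, bool tails, NumericVector x,
                        NumericVector q, NumericVector m,
                        double eps = 1e-6) {
  return loglik(theta.begin(), tails, x, q, m, eps);
}

// Random-walk Metropolis over the active parameters with uniform
// priors on a box (plus the pmin < pmax order constraint). Proposal
// scales adapt during burn-in only, in windows of 100 generations,
// and are frozen afterwards. Uses R's RNG so results are reproducible
// under set.seed().
// [[Rcpp::export(name = ".cline_mcmc_cpp")]]
List cline_mcmc_cpp(NumericVector start, LogicalVector active, bool tails,
                    NumericVector x, NumericVector q, NumericVector m,
                    NumericVector lower, NumericVector upper,
                    NumericVector scale0, int burn_in, int generations,
                    int thin, double eps = 1e-6) {
  const int P = 8;
  std::vector<double> th(start.begin(), start.end());
  std::vector<double> scale(scale0.begin(), scale0.end());
  std::vector<int> acc(P, 0), tot(P, 0), win_acc(P, 0), win_tot(P, 0);

  const int n_keep = generations / thin;
  NumericMatrix draws(n_keep, P);
  NumericVector ll_keep(n_keep);

  double ll = loglik(th.data(), tails, x, q, m, eps);
  int kept = 0;

  for (int g = 0; g < burn_in + generations; ++g) {
    const bool burning = g < burn_in;
    for (int j = 0; j < P; ++j) {
      if (!active[j]) continue;
      const double old = th[j];
      const double prop = old + scale[j] * R::norm_rand();
      bool ok = prop >= lower[j] && prop <= upper[j];
      if (ok && (j == 2 || j == 3)) {
        const double pmin = (j == 2) ? prop : th[2];
        const double pmax = (j == 3) ? prop : th[3];
        ok = pmin < pmax;
      }
      bool accepted = false;
      if (ok) {
        th[j] = prop;
        const double ll_new = loglik(th.data(), tails, x, q, m, eps);
        if (ll_new >= ll || R::unif_rand() < std::exp(ll_new - ll)) {
          ll = ll_new;
          accepted = true;
        } else {
          th[j] = old;
        }
      }
      if (burning) {
        win_tot[j]++;
        if (accepted) win_acc[j]++;
      } else {
        tot[j]++;
        if (accepted) acc[j]++;
      }
    }
    if (burning && (g + 1) % 100 == 0) {
      for (int j = 0; j < P; ++j) {
        if (!active[j] || win_tot[j] == 0) continue;
        const double rate = (double)win_acc[j] / win_tot[j];
        if (rate < 0.15) scale[j] *= 0.7;
        else if (rate > 0.45) scale[j] *= 1.4;
        const double span = upper[j] - lower[j];
        if (scale[j] > span) scale[j] = span;
        if (scale[j] < 1e-9 * std::max(span, 1.0))
          scale[j] = 1e-9 * std::max(span, 1.0);
        win_acc[j] = 0;
        win_tot[j] = 0;
      }
    }
    if (!burning && ((g - burn_in + 1) % thin == 0) && kept < n_keep) {
      for (int j = 0; j < P; ++j) draws(kept, j) = th[j];
      ll_keep[kept] = ll;
      kept++;
    }
  }

  NumericVector acc_rate(P, NA_REAL);
  for (int j = 0; j < P; ++j)
    if (active[j] && tot[j] > 0) acc_rate[j] = (double)acc[j] / tot[j];

  return List::create(_["draws"] = draws, _["loglik"] = ll_keep,
                      _["acceptance"] = acc_rate,
                      _["scales"] = NumericVector(scale.begin(), scale.end()));
}
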