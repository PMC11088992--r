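// Fast path for the per-subject log-likelihood of the joint
// harmful-intent x self-interest belief model. Mirrors the R reference
// implementation (run_subject) cell for cell; tests assert agreement.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double P_EPS = 1e-7;
static const double U_MIN = 1e-3;
static const double U_MAX = 1e6;

static inline double clamp(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// binomial pmf with nb-1 trials, powered by 1/u, renormalized
static void prior_marginal(double p0, double u, int nb, std::vector<double>& out) {
  out.resize(nb);
  double mx = -INFINITY;
  for (int k = 0; k < nb; ++k) {
    out[k] = R::dbinom(k, nb - 1, p0, 1) / u;
    if (out[k] > mx) mx = out[k];
  }
  double s = 0.0;
  for (int k = 0; k < nb; ++k) { out[k] = std::exp(out[k] - mx); s += out[k]; }
  for (int k = 0; k < nb; ++k) out[k] /= s;
}

struct Params {
  double pHI0, pSI0, uPriHI, uPriSI, w0, wHI, wSI, u_pi, eta;
};

static Params expand_theta(const NumericVector& theta, const std::string& variant) {
  Params p;
  if (variant == "M1") {
    if (theta.size() != 9) stop("M1 expects 9 native values");
    p.pHI0 = clamp(logistic(theta[0]), P_EPS, 1 - P_EPS);
    p.pSI0 = clamp(logistic(theta[1]), P_EPS, 1 - P_EPS);
    p.uPriHI = clamp(std::exp(theta[2]), U_MIN, U_MAX);
    p.uPriSI = clamp(std::exp(theta[3]), U_MIN, U_MAX);
    p.w0 = theta[4]; p.wHI = theta[5]; p.wSI = theta[6];
    p.u_pi = clamp(std::exp(theta[7]), U_MIN, U_MAX);
    p.eta = clamp(logistic(theta[8]), P_EPS, 1 - P_EPS);
  } else if (variant == "M2") {
    if (theta.size() != 8) stop("M2 expects 8 native values");
    p.pHI0 = clamp(logistic(theta[0]), P_EPS, 1 - P_EPS);
    p.pSI0 = clamp(logistic(theta[1]), P_EPS, 1 - P_EPS);
    p.uPriHI = clamp(std::exp(theta[2]), U_MIN, U_MAX);
    p.uPriSI = clamp(std::exp(theta[3]), U_MIN, U_MAX);
    p.w0 = theta[4]; p.wHI = theta[5]; p.wSI = theta[5];
    p.u_pi = clamp(std::exp(theta[6]), U_MIN, U_MAX);
    p.eta = clamp(logistic(theta[7]), P_EPS, 1 - P_EPS);
  } else if (variant == "M3") {
    if (theta.size() != 8) stop("M3 expects 8 native values");
    p.pHI0 = clamp(logistic(theta[0]), P_EPS, 1 - P_EPS);
    p.pSI0 = clamp(logistic(theta[1]), P_EPS, 1 - P_EPS);
    p.uPriHI = clamp(std::exp(theta[2]), U_MIN, U_MAX);
    p.uPriSI = p.uPriHI;
    p.w0 = theta[3]; p.wHI = theta[4]; p.wSI = theta[5];
    p.u_pi = clamp(std::exp(theta[6]), U_MIN, U_MAX);
    p.eta = clamp(logistic(theta[7]), P_EPS, 1 - P_EPS);
  } else {
    stop("unknown variant");
  }
  return p;
}

static double subject_ll_impl(const std::vector<double>& th,
                              const std::string& variant,
                              const NumericVector& outcome,
                              const IntegerVector& partner,
                              const IntegerVector& hi_bin,
                              const IntegerVector& si_bin, int nb);

// [[Rcpp::export]]
double cpp_subject_loglik(NumericVector theta, std::string variant,
                          NumericVector outcome, IntegerVector partner,
                          IntegerVector hi_bin, IntegerVector si_bin,
                          int nb = 9) {
  const int n = outcome.size();
  if (n == 0) stop("invalid-input: empty trial list");
  Params p = expand_theta(theta, variant);

  std::vector<double> mhi, msi;
  prior_marginal(p.pHI0, p.uPriHI, nb, mhi);
  prior_marginal(p.pSI0, p.uPriSI, nb, msi);

  const int nc = nb * nb;
  const double delta = (nb + 1) / 2.0;
  const double xi = 0.02 / (nb * nb);
  std::vector<double> prior0(nc), grid(nc), lik0(nc);
  // column-major to match R matrices: index = hi + nb * si
  for (int si = 0; si < nb; ++si)
    for (int hi = 0; hi < nb; ++hi) {
      prior0[hi + nb * si] = mhi[hi] * msi[si];
      lik0[hi + nb * si] =
        logistic(p.w0 + p.wHI * (hi + 1 - delta) + p.wSI * (si + 1 - delta));
    }
  double s0 = 0.0;
  for (int c = 0; c < nc; ++c) s0 += prior0[c];
  for (int c = 0; c < nc; ++c) prior0[c] /= s0;
  grid = prior0;

  const double inv_upi = 1.0 / p.u_pi;
  double total = 0.0;
  for (int t = 0; t < n; ++t) {
    if (t > 0 && partner[t] != partner[t - 1]) {
      double s = 0.0;
      for (int c = 0; c < nc; ++c) {
        grid[c] = prior0[c] * (1.0 - p.eta) + grid[c] * p.eta;
        s += grid[c];
      }
      for (int c = 0; c < nc; ++c) grid[c] /= s;
    }
    const bool unfair = outcome[t] == 0.0;
    double s = 0.0;
    for (int c = 0; c < nc; ++c) {
      grid[c] *= unfair ? lik0[c] : (1.0 - lik0[c]);
      s += grid[c];
    }
    for (int c = 0; c < nc; ++c) grid[c] /= s;
    s = 0.0;
    for (int c = 0; c < nc; ++c) {
      grid[c] = std::pow(grid[c], inv_upi) + xi;
      s += grid[c];
    }
    for (int c = 0; c < nc; ++c) grid[c] /= s;
    double cell = grid[(hi_bin[t] - 1) + nb * (si_bin[t] - 1)];
    total += std::log(cell > 1e-12 ? cell : 1e-12);
  }
  return total;
}

static double subject_ll_impl(const std::vector<double>& th,
                              const std::string& variant,
                              const NumericVector& outcome,
                              const IntegerVector& partner,
                              const IntegerVector& hi_bin,
                              const IntegerVector& si_bin, int nb) {
  NumericVector tv(th.begin(), th.end());
  return cpp_subject_loglik(tv, variant, outcome, partner, hi_bin, si_bin, nb);
}

// Gradient of the negative log joint (-loglik - logprior) in native space:
// central differences for the likelihood term, analytic for the Gaussian
// prior. Used as the quasi-Newton gradient callback.
// [[Rcpp::export]]
NumericVector cpp_subject_negobj_grad(NumericVector theta, std::string variant,
                                      NumericVector outcome, IntegerVector partner,
                                      IntegerVector hi_bin, IntegerVector si_bin,
                                      NumericVector mu, NumericVector sd,
                                      int nb = 9, double h = 1e-5) {
  const int d = theta.size();
  NumericVector g(d);
  std::vector<double> th(theta.begin(), theta.end());
  for (int j = 0; j < d; ++j) {
    const double orig = th[j];
    th[j] = orig + h;
    double up = subject_ll_impl(th, variant, outcome, partner, hi_bin, si_bin, nb);
    th[j] = orig - h;
    double dn = subject_ll_impl(th, variant, outcome, partner, hi_bin, si_bin, nb);
    th[j] = orig;
    g[j] = -(up - dn) / (2.0 * h) + (orig - mu[j]) / (sd[j] * sd[j]);
  }
  return g;
}
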