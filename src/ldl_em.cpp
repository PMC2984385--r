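#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// EM maximisation of the half-sib QTL mixture likelihood at one tested
// position. Under the additive constraint the individual likelihood is a
// three-component Gaussian mixture over the progeny's transmitted QTL
// dose g in {+1, 0, -1} (relative to one Q and one q copy):
//   L_j = sum_g w_g(j) * phi(y_j; mu_{sire(j)} + alpha * g, sigma2)
// with mixing weights built from the probability pS_j that the sire
// transmitted Q and the probability pd_j that the dam transmitted Q:
//   w_{+1} = pS pd, w_0 = pS (1-pd) + (1-pS) pd, w_{-1} = (1-pS)(1-pd).
// Sire means, the substitution effect alpha and sigma2 are maximised by
// conditional M-steps (monotone ECM); several deterministic alpha starts
// guard against local optima. Returns the best fit over starts.

// [[Rcpp::export]]
List ldl_em_fit(NumericVector y, IntegerVector sire, int n_sire,
                NumericVector pS, NumericVector pd,
                NumericVector alpha_starts, NumericVector mu0,
                double sigma2_0, double tol, int maxit) {
  const int n = y.size();
  std::vector<double> w1(n), w0(n), wm(n);
  for (int j = 0; j < n; ++j) {
    double a = pS[j], b = pd[j];
    if (a < 0) a = 0; if (a > 1) a = 1;
    if (b < 0) b = 0; if (b > 1) b = 1;
    w1[j] = a * b;
    w0[j] = a * (1 - b) + (1 - a) * b;
    wm[j] = (1 - a) * (1 - b);
  }
  std::vector<int> cnt(n_sire, 0);
  for (int j = 0; j < n; ++j) cnt[sire[j] - 1]++;

  double best_ll = R_NegInf, best_alpha = 0, best_sig2 = sigma2_0;
  NumericVector best_mu(clone(mu0));

  std::vector<double> mu(n_sire), r1(n), r0(n), rm(n);
  for (int s = 0; s < alpha_starts.size(); ++s) {
    for (int i = 0; i < n_sire; ++i) mu[i] = mu0[i];
    double alpha = alpha_starts[s], sig2 = sigma2_0;
    double ll = R_NegInf, ll_old = R_NegInf;
    double cur_alpha = alpha, cur_sig2 = sig2;
    std::vector<double> cur_mu(mu);
    for (int it = 0; it < maxit; ++it) {
      // E-step and log-likelihood at current parameters
      double inv2s = 1.0 / (2.0 * sig2);
      double lognorm = -0.5 * std::log(2.0 * M_PI * sig2);
      // (y - m -/+ alpha)^2 = e0^2 -/+ 2 alpha e0 + alpha^2: the outer
      // components need only one extra exponential via u = exp(alpha e0 / s)
      double ka = std::exp(-alpha * alpha * inv2s);
      ll = 0.0;
      for (int j = 0; j < n; ++j) {
        double m = mu[sire[j] - 1];
        double e0 = y[j] - m;
        double d0 = std::exp(-e0 * e0 * inv2s);
        double u = std::exp(2.0 * alpha * e0 * inv2s);
        double d1 = w1[j] * d0 * ka * u;
        double dm = wm[j] * d0 * ka / u;
        d0 *= w0[j];
        double L = d1 + d0 + dm;
        if (L <= 0 || !std::isfinite(L)) { L = 1e-300; d0 = L; d1 = dm = 0; }
        ll += std::log(L) + lognorm;
        r1[j] = d1 / L; r0[j] = d0 / L; rm[j] = dm / L;
      }
      cur_alpha = alpha; cur_sig2 = sig2; cur_mu = mu;
      if (std::isfinite(ll_old) && std::fabs(ll - ll_old) < tol) break;
      ll_old = ll;
      // CM-step 1: sire means given alpha
      std::vector<double> smu(n_sire, 0.0);
      for (int j = 0; j < n; ++j) {
        smu[sire[j] - 1] += y[j] - alpha * (r1[j] - rm[j]);
      }
      for (int i = 0; i < n_sire; ++i) {
        if (cnt[i] > 0) mu[i] = smu[i] / cnt[i];
      }
      // CM-step 2: alpha given means
      double numa = 0.0, dena = 0.0;
      for (int j = 0; j < n; ++j) {
        double m = mu[sire[j] - 1];
        numa += (r1[j] - rm[j]) * (y[j] - m);
        dena += r1[j] + rm[j];
      }
      if (dena > 1e-12) alpha = numa / dena;
      // CM-step 3: variance
      double ss = 0.0;
      for (int j = 0; j < n; ++j) {
        double m = mu[sire[j] - 1];
        double e1 = y[j] - m - alpha, e0 = y[j] - m, em = y[j] - m + alpha;
        ss += r1[j] * e1 * e1 + r0[j] * e0 * e0 + rm[j] * em * em;
      }
      sig2 = ss / n;
      if (sig2 < 1e-6) sig2 = 1e-6;
    }
    if (ll > best_ll) {
      best_ll = ll; best_alpha = cur_alpha; best_sig2 = cur_sig2;
      for (int i = 0; i < n_sire; ++i) best_mu[i] = cur_mu[i];
    }
  }
  return List::create(_["loglik"] = best_ll, _["alpha"] = best_alpha,
                      _["sigma2"] = best_sig2, _["mu"] = best_mu);
}
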