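// Binomial negative log-likelihood of the 4PL dose-response model and of
// its profile reparameterization, with analytic gradients. These are the
// innermost functions of every fit; the band algorithm performs thousands
// of constrained optimizations, so they are kept in C++.
#include <Rcpp.h>
using namespace Rcpp;

static const double EPS = 1e-12;   // probability clamp before taking logs
static const double ZCAP = 700.0;  // exponent cap: saturate to the asymptote

static inline double clamp01(double p) {
  if (p < EPS) return EPS;
  if (p > 1.0 - EPS) return 1.0 - EPS;
  return p;
}

// y*log(p) + (N-y)*log(1-p) with the clamp; binomial coefficient omitted
static inline double loglik_term(double y, double N, double p) {
  p = clamp01(p);
  return y * std::log(p) + (N - y) * std::log1p(-p);
}

// derivative of the term in p; zero where the probability is clamped
static inline double loglik_weight(double y, double N, double p) {
  if (p <= EPS || p >= 1.0 - EPS) return 0.0;
  return y / p - (N - y) / (1.0 - p);
}

// [[Rcpp::export]]
double cpp_nll_fourpl(NumericVector th, NumericVector dose,
                      NumericVector y, NumericVector N) {
  double p0 = th[0], Emax = th[1], ED50 = th[2], delta = th[3];
  double nll = 0.0;
  for (int i = 0; i < dose.size(); ++i) {
    double z = (ED50 - dose[i]) / delta;
    if (z > ZCAP) z = ZCAP;
    double p = p0 + Emax / (1.0 + std::exp(z));
    nll -= loglik_term(y[i], N[i], p);
  }
  double v = p0 + Emax - 1.0;
  if (v > 0.0) nll += 1e6 * v * v;
  return nll;
}

// [[Rcpp::export]]
NumericVector cpp_nll_fourpl_grad(NumericVector th, NumericVector dose,
                                  NumericVector y, NumericVector N) {
  double p0 = th[0], Emax = th[1], ED50 = th[2], delta = th[3];
  NumericVector g(4);
  for (int i = 0; i < dose.size(); ++i) {
    double z = (ED50 - dose[i]) / delta;
    bool capped = z > ZCAP;
    if (capped) z = ZCAP;
    double E = std::exp(z), B = 1.0 + E;
    double p = p0 + Emax / B;
    double w = loglik_weight(y[i], N[i], p);
    double dE = capped ? 0.0 : E;
    g[0] -= w;
    g[1] -= w / B;
    g[2] -= w * (-Emax * dE / (delta * B * B));
    g[3] -= w * (Emax * dE * z / (delta * B * B));
  }
  double v = p0 + Emax - 1.0;
  if (v > 0.0) { g[0] += 2e6 * v; g[1] += 2e6 * v; }
  return g;
}

// Profile objective in th = (Emax, ED50, delta): the basal effect is
// eliminated as p0 = pstar - Emax / A with A = 1 + exp((ED50-dstar)/delta),
// so the curve passes exactly through (dstar, pstar). Penalties keep
// p0 >= 0 and p0 + Emax <= 1.
// [[Rcpp::export]]
double cpp_nll_profile(NumericVector th, NumericVector dose,
                       NumericVector y, NumericVector N,
                       double dstar, double pstar) {
  double Emax = th[0], ED50 = th[1], delta = th[2];
  double zs = (ED50 - dstar) / delta;
  if (zs > ZCAP) zs = ZCAP;
  double A = 1.0 + std::exp(zs);
  double p0 = pstar - Emax / A;
  double nll = 0.0;
  for (int i = 0; i < dose.size(); ++i) {
    double z = (ED50 - dose[i]) / delta;
    if (z > ZCAP) z = ZCAP;
    double p = p0 + Emax / (1.0 + std::exp(z));
    nll -= loglik_term(y[i], N[i], p);
  }
  if (p0 < 0.0) nll += 1e6 * p0 * p0;
  double v = p0 + Emax - 1.0;
  if (v > 0.0) nll += 1e6 * v * v;
  return nll;
}

// [[Rcpp::export]]
NumericVector cpp_nll_profile_grad(NumericVector th, NumericVector dose,
                                   NumericVector y, NumericVector N,
                                   double dstar, double pstar) {
  double Emax = th[0], ED50 = th[1], delta = th[2];
  double zs = (ED50 - dstar) / delta;
  bool cap_s = zs > ZCAP;
  if (cap_s) zs = ZCAP;
  double Es = std::exp(zs), A = 1.0 + Es;
  double dEs = cap_s ? 0.0 : Es;
  double p0 = pstar - Emax / A;
  // d p0 / d (Emax, ED50, delta)
  double dp0_E = -1.0 / A;
  double dp0_D = Emax * dEs / (delta * A * A);
  double dp0_d = -Emax * dEs * zs / (delta * A * A);
  NumericVector g(3);
  for (int i = 0; i < dose.size(); ++i) {
    double z = (ED50 - dose[i]) / delta;
    bool capped = z > ZCAP;
    if (capped) z = ZCAP;
    double E = std::exp(z), B = 1.0 + E;
    double dE = capped ? 0.0 : E;
    double p = p0 + Emax / B;
    double w = loglik_weight(y[i], N[i], p);
    g[0] -= w * (dp0_E + 1.0 / B);
    g[1] -= w * (dp0_D - Emax * dE / (delta * B * B));
    g[2] -= w * (dp0_d + Emax * dE * z / (delta * B * B));
  }
  if (p0 < 0.0) {
    g[0] += 2e6 * p0 * dp0_E;
    g[1] += 2e6 * p0 * dp0_D;
    g[2] += 2e6 * p0 * dp0_d;
  }
  double v = p0 + Emax - 1.0;
  if (v > 0.0) {
    g[0] += 2e6 * v * (dp0_E + 1.0);
    g[1] += 2e6 * v * dp0_D;
    g[2] += 2e6 * v * dp0_d;
  }
  return g;
}
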