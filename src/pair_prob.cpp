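// Inner kernels of the simulated Type 2 likelihood.  These are called
// hundreds of times per fit over (pairs x bank draws)-sized vectors, so
// they live in C++; the R wrappers in R/models.R keep identical
// semantics and the test suite cross-checks both against Monte-Carlo
// oracles.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// standard normal CDF via erfc (accurate to ~1e-15, much faster than the
// general-purpose pnorm)
static inline double phi(double z) {
  return 0.5 * std::erfc(-z * M_SQRT1_2);
}

// P(|N(d2, s^2)| + k2 > |N(d1, s^2)|) by Gauss-Hermite quadrature over
// the interval-1 variable; gh nodes/weights are supplied pre-normalised
// (weights sum to 1, nodes on the standard scale).
// [[Rcpp::export(name = ".folded_pair_prob")]]
NumericVector folded_pair_prob(NumericVector d1, NumericVector d2,
                               double k2, double sigma,
                               NumericVector gh_x, NumericVector gh_w) {
  const R_xlen_t n = d1.size();
  const int m = gh_x.size();
  NumericVector out(n);
  const double s2 = std::sqrt(2.0) * sigma;
  for (R_xlen_t i = 0; i < n; ++i) {
    double p = 0.0;
    for (int j = 0; j < m; ++j) {
      double t = std::fabs(d1[i] + s2 * gh_x[j]) - k2;
      if (t < 0.0) t = 0.0;
      double surv = 1.0 - (phi((t - d2[i]) / sigma) -
                           phi((-t - d2[i]) / sigma));
      p += gh_w[j] * surv;
    }
    out[i] = p;
  }
  return out;
}

// Tabulated beta-noise comparison used inside the fitting loop:
// given per-draw quantile ladders Q1, Q2 (rows = draws, columns =
// increasing probability levels u, the first and last columns being
// near-tail anchors used only for CDF interpolation), returns
// P(w2 + k2 > w1) by a midpoint rule over the interior w2 quantiles
// with the w1 CDF piecewise-linearised through its ladder.
// [[Rcpp::export(name = ".beta_pair_prob_tab")]]
NumericVector beta_pair_prob_tab(NumericMatrix Q1, NumericMatrix Q2,
                                 NumericVector u, IntegerVector interior,
                                 double k2) {
  const int n = Q1.nrow(), m = u.size(), li = interior.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double p = 0.0;
    for (int li_ = 0; li_ < li; ++li_) {   // midpoint levels of w2
      double t = Q2(i, interior[li_] - 1) + k2;
      double F;
      if (t <= Q1(i, 0)) {
        F = 0.0;
      } else if (t >= Q1(i, m - 1)) {
        F = 1.0;
      } else {
        int j = 0;
        while (j < m - 1 && Q1(i, j + 1) < t) ++j;
        double q0 = Q1(i, j), q1 = Q1(i, j + 1);
        double w = (q1 > q0) ? (t - q0) / (q1 - q0) : 0.5;
        F = u[j] + w * (u[j + 1] - u[j]);
      }
      p += F;
    }
    out[i] = p / li;
  }
  return out;
}

// P(w2 + k2 > w1), w_i ~ Beta(nu p_i, nu (1 - p_i)), by a quantile grid
// over w2 (midpoint rule on the probability scale).
// [[Rcpp::export(name = ".beta_pair_prob")]]
NumericVector beta_pair_prob(NumericVector p1, NumericVector p2,
                             double nu, double k2, NumericVector u) {
  const R_xlen_t n = p1.size();
  const int m = u.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double a1 = nu * p1[i], b1 = nu * (1.0 - p1[i]);
    double a2 = nu * p2[i], b2 = nu * (1.0 - p2[i]);
    double p = 0.0;
    for (int j = 0; j < m; ++j) {
      double q2 = R::qbeta(u[j], a2, b2, 1, 0);
      double t = q2 + k2;
      if (t <= 0.0) continue;
      if (t >= 1.0) { p += 1.0; continue; }
      p += R::pbeta(t, a1, b1, 1, 0);
    }
    out[i] = p / m;
  }
  return out;
}
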