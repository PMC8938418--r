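// Gibbs-within-Metropolis sampler for the phylogenetic threshold model.
//
// Latent liabilities L = (x-liabilities, y-liabilities) of one gene pair are
// jointly MVN(0, Sigma (x) C) where C is the tree's Brownian covariance and
// Sigma = [[1, r], [r, 1]]. Observed binary states fix the sign of each tip
// liability. Each sweep resamples every liability from its conditional
// normal truncated to the observed sign, then proposes r by random walk
// under a uniform(-1, 1) prior. Uses R's RNG so runs are reproducible under
// set.seed().

#include <Rcpp.h>
using namespace Rcpp;

// one-sided truncated normal: N(m, s) conditioned on > 0 (sign = +1) or
// < 0 (sign = -1); inverse CDF in the body, exponential rejection
// (Robert 1995) in the far tail
static double rtnorm_sign(double m, double s, int sign) {
  double a = (sign > 0) ? (-m / s) : (m / s); // standardized lower bound
  double z;
  if (a < 5.0) {
    double lo = R::pnorm(a, 0.0, 1.0, 1, 0);
    double u = R::runif(lo, 1.0);
    if (u > 1.0 - 1e-16) u = 1.0 - 1e-16;
    if (u < 1e-300) u = 1e-300;
    z = R::qnorm(u, 0.0, 1.0, 1, 0);
  } else {
    double lam = 0.5 * (a + std::sqrt(a * a + 4.0));
    for (;;) {
      double cand = a + R::rexp(1.0) / lam;
      double d = cand - lam;
      if (R::runif(0.0, 1.0) <= std::exp(-0.5 * d * d)) { z = cand; break; }
    }
  }
  return (sign > 0) ? (m + s * z) : (m - s * z);
}

// [[Rcpp::export(name = ".liabilityMcmcCpp")]]
List liabilityMcmcCpp(NumericMatrix Cinv, IntegerVector sgn,
                      int iterations, int keepFrom, int thin,
                      double proposalSd) {
  int n = Cinv.nrow();
  int m2 = 2 * n;
  std::vector<double> L(m2);
  for (int i = 0; i < m2; ++i) L[i] = 0.7 * sgn[i];

  double r = 0.0;
  // Q = Sinv (x) Cinv with Sinv = [[1,-r],[-r,1]]/(1-r^2)
  std::vector<double> Q(m2 * m2);
  auto buildQ = [&](double rr, std::vector<double> &QQ) {
    double d = 1.0 - rr * rr;
    double s11 = 1.0 / d, s12 = -rr / d;
    for (int a = 0; a < n; ++a)
      for (int b = 0; b < n; ++b) {
        double c = Cinv(a, b);
        QQ[a * m2 + b] = s11 * c;
        QQ[a * m2 + (n + b)] = s12 * c;
        QQ[(n + a) * m2 + b] = s12 * c;
        QQ[(n + a) * m2 + (n + b)] = s11 * c;
      }
  };
  buildQ(r, Q);

  auto quad = [&](const std::vector<double> &QQ) {
    double acc = 0.0;
    for (int i = 0; i < m2; ++i) {
      double row = 0.0;
      const double *qi = &QQ[i * m2];
      for (int j = 0; j < m2; ++j) row += qi[j] * L[j];
      acc += L[i] * row;
    }
    return acc;
  };

  std::vector<double> Qprop(m2 * m2);
  int nKeep = 0;
  for (int it = keepFrom; it < iterations; ++it)
    if ((it + 1) % thin == 0) ++nKeep;
  NumericVector samples(nKeep);
  int si = 0, acc = 0;

  for (int it = 0; it < iterations; ++it) {
    for (int i = 0; i < m2; ++i) {
      const double *qi = &Q[i * m2];
      double dot = 0.0;
      for (int j = 0; j < m2; ++j) dot += qi[j] * L[j];
      double qii = qi[i];
      double mu = L[i] - dot / qii;
      double sd = std::sqrt(1.0 / qii);
      L[i] = rtnorm_sign(mu, sd, sgn[i]);
    }
    double rProp = r + R::norm_rand() * proposalSd;
    if (rProp > -1.0 && rProp < 1.0) {
      buildQ(rProp, Qprop);
      double lpNew = -0.5 * quad(Qprop) -
        0.5 * n * std::log(1.0 - rProp * rProp);
      double lpOld = -0.5 * quad(Q) - 0.5 * n * std::log(1.0 - r * r);
      if (std::log(R::unif_rand()) < lpNew - lpOld) {
        r = rProp;
        std::swap(Q, Qprop);
        ++acc;
      }
    }
    if (it >= keepFrom && (it + 1) % thin == 0) samples[si++] = r;
  }
  return List::create(_["samples"] = samples,
                      _["acceptance"] = double(acc) / iterations);
}
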