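#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Origin-fixation evolution of the mean phenotype of two traits.
//
// Per unit time a Poisson(mut_rate) number of mutations arises; each effect
// is a bivariate normal draw (Cholesky factors l11, l21, l22 of the
// mutational covariance matrix M), optionally rescaled by the bias
// coefficient (both components multiplied by `bias` when the first trait's
// effect is positive, divided when negative). Mutations are evaluated
// sequentially: the selection coefficient is s = f(mean + m)/f(mean) - 1
// under Gaussian fitness f = exp(-D^2/2), the fixation probability is
// Kimura's haploid (1 - exp(-2s))/(1 - exp(-2*Ne*s)), and the effect is
// added to the mean with probability min(1, Ne * Pf) before the next
// mutation of the same time unit is evaluated. Regimes: 0 = none (every
// mutation fixes: Ne * (1/Ne) = 1), 1 = ridge y = slope * x (D = distance
// to the line), 2 = fixed point optimum, 3 = per-lineage optima supplied in
// `optima`.
//
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix cpp_evolve_lineages(int n_lineages, int time_units,
                                  double l11, double l21, double l22,
                                  double ne, double mut_rate, int regime,
                                  double slope, double opt1, double opt2,
                                  NumericMatrix optima, double bias) {
  NumericMatrix out(n_lineages, 2);
  const double ridge_norm = std::sqrt(1.0 + slope * slope);
  for (int i = 0; i < n_lineages; ++i) {
    double x = 0.0, y = 0.0;
    double o1 = opt1, o2 = opt2;
    if (regime == 3) { o1 = optima(i, 0); o2 = optima(i, 1); }
    for (int t = 0; t < time_units; ++t) {
      int nmut = (int) R::rpois(mut_rate);
      for (int k = 0; k < nmut; ++k) {
        double z1 = R::norm_rand(), z2 = R::norm_rand();
        double m1 = l11 * z1;
        double m2 = l21 * z1 + l22 * z2;
        if (bias != 1.0) {
          if (m1 > 0)      { m1 *= bias; m2 *= bias; }
          else if (m1 < 0) { m1 /= bias; m2 /= bias; }
        }
        if (regime == 0) { x += m1; y += m2; continue; }
        double d0sq, d1sq;
        if (regime == 1) {
          double r0 = (y - slope * x) / ridge_norm;
          double r1 = ((y + m2) - slope * (x + m1)) / ridge_norm;
          d0sq = r0 * r0;
          d1sq = r1 * r1;
        } else {
          double dx = x - o1, dy = y - o2;
          d0sq = dx * dx + dy * dy;
          dx = x + m1 - o1; dy = y + m2 - o2;
          d1sq = dx * dx + dy * dy;
        }
        // s = f_mut/f_wt - 1 = exp(-(D1^2 - D0^2)/2) - 1
        double s = std::expm1(-(d1sq - d0sq) / 2.0);
        double pf;
        if (std::fabs(s) < 1e-12) {
          pf = 1.0 / ne;
        } else {
          double num = -std::expm1(-2.0 * s);
          double den = -std::expm1(-2.0 * ne * s);
          pf = std::isinf(den) ? 0.0 : num / den;
        }
        double acc = ne * pf;
        if (acc >= 1.0 || R::unif_rand() < acc) { x += m1; y += m2; }
      }
    }
    out(i, 0) = x;
    out(i, 1) = y;
  }
  return out;
}
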