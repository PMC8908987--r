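// Orthonormal real spherical-harmonic basis evaluated at a set of sphere
// points. Normalized associated Legendre functions are computed with the
// standard stable three-term recurrence (no Condon-Shortley phase), so
// high orders are safe from overflow. Column layout: blocks of order
// l = 0..lmax, within a block m = -l..l (sine terms for m < 0, the zonal
// term at m = 0, cosine terms for m > 0).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_sh_basis(NumericVector costheta, NumericVector phi,
                           int lmax) {
  int n = costheta.size();
  int ncol = (lmax + 1) * (lmax + 1);
  NumericMatrix Y(n, ncol);
  const double sq2 = std::sqrt(2.0);

  for (int p = 0; p < n; ++p) {
    double ct = costheta[p];
    if (ct > 1) ct = 1; if (ct < -1) ct = -1;
    double st = std::sqrt(1.0 - ct * ct);
    double ph = phi[p];

    double seed = std::sqrt(1.0 / (4.0 * M_PI)); // P~_0^0
    for (int m = 0; m <= lmax; ++m) {
      if (m > 0)
        seed *= st * std::sqrt((2.0 * m + 1.0) / (2.0 * m));
      const double cm = std::cos(m * ph), sm = std::sin(m * ph);
      double prev2 = 0.0, prev = seed; // P~_{l-2}^m, P~_{l-1}^m
      for (int l = m; l <= lmax; ++l) {
        double cur;
        if (l == m) cur = seed;
        else if (l == m + 1) cur = std::sqrt(2.0 * m + 3.0) * ct * prev;
        else {
          double a = std::sqrt((4.0 * l * l - 1.0) /
                               ((double)l * l - (double)m * m));
          double b = std::sqrt((((double)(l - 1) * (l - 1)) - (double)m * m) /
                               (4.0 * (double)(l - 1) * (l - 1) - 1.0));
          cur = a * (ct * prev - b * prev2);
        }
        int center = l * l + l; // m = 0 position of the order-l block
        if (m == 0) {
          Y(p, center) = cur;
        } else {
          Y(p, center + m) = sq2 * cur * cm;
          Y(p, center - m) = sq2 * cur * sm;
        }
        if (l > m) prev2 = prev;
        prev = cur;
      }
    }
  }
  return Y;
}
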