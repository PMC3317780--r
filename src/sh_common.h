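#ifndef TRACTREPRO_SH_COMMON_H
#define TRACTREPRO_SH_COMMON_H

#include <cmath>
#include <vector>
#include <algorithm>

namespace trsh {

inline int n_coeffs(int lmax) { return (lmax + 1) * (lmax + 2) / 2; }

// Associated Legendre P_l^m(x) for fixed x, all l<=lmax, m<=l.
// plm must have room for (lmax+1)*(lmax+1); index [l*(lmax+1)+m].
inline void legendre_table(double x, int lmax, double* plm) {
  const double somx2 = std::sqrt(std::max(0.0, 1.0 - x * x));
  const int L = lmax + 1;
  for (int m = 0; m <= lmax; ++m) {
    // P_m^m
    double pmm = 1.0;
    if (m > 0) {
      double fact = 1.0;
      for (int i = 1; i <= m; ++i) {
        pmm *= -fact * somx2;  // Condon-Shortley phase
        fact += 2.0;
      }
    }
    plm[m * L + m] = pmm;
    if (m < lmax) {
      double pmmp1 = x * (2 * m + 1) * pmm;
      plm[(m + 1) * L + m] = pmmp1;
      double pll = 0.0;
      for (int l = m + 2; l <= lmax; ++l) {
        pll = (x * (2 * l - 1) * pmmp1 - (l + m - 1) * plm[(l - 2) * L + m]) /
              (double)(l - m);
        plm[l * L + m] = pll;
        pmmp1 = pll;
      }
    }
  }
}

// normalization constants sqrt((2l+1)/(4 pi) (l-m)!/(l+m)!), cached per lmax
inline const std::vector<double>& norm_table(int lmax) {
  static std::vector<double> cache;
  static int cached_lmax = -1;
  if (lmax != cached_lmax) {
    const int L = lmax + 1;
    cache.assign(L * L, 0.0);
    for (int l = 0; l <= lmax; ++l) {
      for (int m = 0; m <= l; ++m) {
        double lnn = 0.0;  // log of (l-m)!/(l+m)!
        for (int i = l - m + 1; i <= l + m; ++i) lnn -= std::log((double)i);
        cache[l * L + m] =
            std::sqrt((2.0 * l + 1.0) / (4.0 * M_PI) * std::exp(lnn));
      }
    }
    cached_lmax = lmax;
  }
  return cache;
}

// Evaluate the full even-order basis row at a unit direction d (length 3).
// out must have room for n_coeffs(lmax).
inline void basis_row(const double* d, int lmax, double* out) {
  const double z = std::max(-1.0, std::min(1.0, d[2]));
  const double phi = std::atan2(d[1], d[0]);
  const int L = lmax + 1;
  double plm[17 * 17];
  legendre_table(z, lmax, plm);
  const std::vector<double>& norms = norm_table(lmax);

  double cosm[17], sinm[17];
  for (int m = 0; m <= lmax; ++m) {
    cosm[m] = std::cos(m * phi);
    sinm[m] = std::sin(m * phi);
  }
  int j = 0;
  for (int l = 0; l <= lmax; l += 2) {
    for (int m = -l; m <= l; ++m) {
      const int am = std::abs(m);
      const double np = norms[l * L + am] * plm[l * L + am];
      double val;
      if (m < 0)
        val = M_SQRT2 * np * sinm[am];
      else if (m == 0)
        val = np;
      else
        val = M_SQRT2 * np * cosm[m];
      out[j++] = val;
    }
  }
}

inline double amplitude(const double* d, const double* coef, int lmax,
                        double* scratch) {
  basis_row(d, lmax, scratch);
  const int nc = n_coeffs(lmax);
  double a = 0.0;
  for (int j = 0; j < nc; ++j) a += scratch[j] * coef[j];
  return a;
}

}  // namespace trsh

#endif
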