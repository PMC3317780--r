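// Real, orthonormal, even-order spherical harmonics.
//
// Basis convention (shared by every module and by serialization metadata):
//   * even degrees l = 0, 2, ..., lmax only (diffusion signal and FODs are
//     antipodally symmetric);
//   * coefficient ordering: l ascending, then m ascending from -l to +l;
//   * real basis
//       Y_{l,m<0} = sqrt(2) N_l^{|m|} P_l^{|m|}(cos th) sin(|m| phi)
//       Y_{l,0}   =          N_l^{0}  P_l^{0}(cos th)
//       Y_{l,m>0} = sqrt(2) N_l^{m}   P_l^{m}(cos th) cos(m phi)
//     with N_l^m = sqrt((2l+1)/(4 pi) * (l-m)!/(l+m)!) and associated
//     Legendre functions including the Condon-Shortley phase.
// The basis is orthonormal under the surface measure on the unit sphere.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

#include "sh_common.h"

// [[Rcpp::export(name = ".sh_basis_cpp")]]
NumericMatrix sh_basis_cpp(NumericMatrix dirs, int lmax) {
  const int n = dirs.nrow();
  const int nc = trsh::n_coeffs(lmax);
  NumericMatrix out(n, nc);
  std::vector<double> row(nc);
  double d[3];
  for (int i = 0; i < n; ++i) {
    d[0] = dirs(i, 0); d[1] = dirs(i, 1); d[2] = dirs(i, 2);
    trsh::basis_row(d, lmax, row.data());
    for (int j = 0; j < nc; ++j) out(i, j) = row[j];
  }
  return out;
}
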