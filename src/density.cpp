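// Exact streamline-to-grid traversal.
//
// For one streamline (ordered world-mm points), returns the unique set of
// grid elements its polyline passes through.  Each segment is cut at every
// voxel boundary-plane crossing (voxel-center convention: boundaries at
// half-integer voxel coordinates) and the midpoint of every sub-interval is
// assigned to its containing element, which is exact for axis-aligned boxes.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".visit_elements_cpp")]]
IntegerVector visit_elements_cpp(NumericMatrix points, NumericMatrix w2v,
                                 IntegerVector dims) {
  const int n = points.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> v(3 * n);
  for (int i = 0; i < n; ++i) {
    for (int r = 0; r < 3; ++r) {
      v[3 * i + r] = w2v(r, 0) * points(i, 0) + w2v(r, 1) * points(i, 1) +
                     w2v(r, 2) * points(i, 2) + w2v(r, 3);
    }
  }
  std::vector<long> visited;
  auto push_voxel = [&](const double* p) {
    const long ix = std::lround(p[0]);
    const long iy = std::lround(p[1]);
    const long iz = std::lround(p[2]);
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz)
      return;
    visited.push_back(1 + ix + (long)nx * (iy + (long)ny * iz));
  };
  if (n == 1) push_voxel(&v[0]);
  std::vector<double> ts;
  for (int i = 0; i + 1 < n; ++i) {
    const double* a = &v[3 * i];
    const double* b = &v[3 * (i + 1)];
    ts.clear();
    ts.push_back(0.0);
    ts.push_back(1.0);
    for (int ax = 0; ax < 3; ++ax) {
      const double d = b[ax] - a[ax];
      if (std::fabs(d) < 1e-12) continue;
      const long lo = (long)std::floor(std::min(a[ax], b[ax]) + 0.5);
      const long hi = (long)std::ceil(std::max(a[ax], b[ax]) + 0.5);
      for (long k = lo; k <= hi; ++k) {
        const double bound = k - 0.5;  // boundary plane between voxels
        const double t = (bound - a[ax]) / d;
        if (t > 0.0 && t < 1.0) ts.push_back(t);
      }
    }
    std::sort(ts.begin(), ts.end());
    for (size_t j = 0; j + 1 < ts.size(); ++j) {
      const double tm = 0.5 * (ts[j] + ts[j + 1]);
      double p[3] = {a[0] + tm * (b[0] - a[0]), a[1] + tm * (b[1] - a[1]),
                     a[2] + tm * (b[2] - a[2])};
      push_voxel(p);
    }
  }
  std::sort(visited.begin(), visited.end());
  visited.erase(std::unique(visited.begin(), visited.end()), visited.end());
  return IntegerVector(visited.begin(), visited.end());
}
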