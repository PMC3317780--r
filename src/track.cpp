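// Probabilistic streamline propagation by FOD rejection sampling.
//
// One call grows a single bidirectional streamline from a world-space seed:
// an initial direction is drawn from the FOD over the whole sphere, then two
// half-tracks are grown (along +d0 and -d0) with fixed step length and a
// curvature-limited cone for each new direction.  SH coefficients are
// trilinearly interpolated at off-grid positions; all geometry is in world mm.
//
// Uses R's RNG (unif_rand) so results are reproducible under set.seed().

#include <Rcpp.h>
#include "sh_common.h"
using namespace Rcpp;

namespace {

struct Field {
  const double* coef;   // coefficient-first layout: (nc, nx, ny, nz)
  const int* brain;     // (nx,ny,nz)
  const int* target;    // (nx,ny,nz) 0 = none
  int nx, ny, nz, nc;
  const double* w2v;    // 4x4 column-major world -> 0-based voxel coords
};

inline void world2vox(const Field& f, const double* p, double* v) {
  for (int r = 0; r < 3; ++r)
    v[r] = f.w2v[r] * p[0] + f.w2v[r + 4] * p[1] + f.w2v[r + 8] * p[2] +
           f.w2v[r + 12];
}

inline bool voxel_index(const Field& f, const double* p, int* idx) {
  double v[3];
  world2vox(f, p, v);
  for (int a = 0; a < 3; ++a) idx[a] = (int)std::lround(v[a]);
  return idx[0] >= 0 && idx[0] < f.nx && idx[1] >= 0 && idx[1] < f.ny &&
         idx[2] >= 0 && idx[2] < f.nz;
}

inline bool in_brain(const Field& f, const double* p) {
  int idx[3];
  if (!voxel_index(f, p, idx)) return false;
  return f.brain[idx[0] + f.nx * (idx[1] + (long)f.ny * idx[2])] != 0;
}

inline int target_at(const Field& f, const double* p) {
  int idx[3];
  if (!voxel_index(f, p, idx)) return 0;
  return f.target[idx[0] + f.nx * (idx[1] + (long)f.ny * idx[2])];
}

// Trilinear interpolation of the coefficient vector; zero outside the grid.
inline void interp_coefs(const Field& f, const double* p, double* out) {
  double v[3];
  world2vox(f, p, v);
  for (int j = 0; j < f.nc; ++j) out[j] = 0.0;
  int i0[3];
  double fr[3];
  for (int a = 0; a < 3; ++a) {
    i0[a] = (int)std::floor(v[a]);
    fr[a] = v[a] - i0[a];
  }
  for (int c = 0; c < 8; ++c) {
    const int dx = c & 1, dy = (c >> 1) & 1, dz = (c >> 2) & 1;
    const int x = i0[0] + dx, y = i0[1] + dy, z = i0[2] + dz;
    if (x < 0 || x >= f.nx || y < 0 || y >= f.ny || z < 0 || z >= f.nz)
      continue;
    const double w = (dx ? fr[0] : 1 - fr[0]) * (dy ? fr[1] : 1 - fr[1]) *
                     (dz ? fr[2] : 1 - fr[2]);
    if (w <= 0) continue;
    const double* cj = f.coef + (long)f.nc * (x + f.nx * (y + (long)f.ny * z));
    for (int j = 0; j < f.nc; ++j) out[j] += w * cj[j];
  }
}

inline void unit_sphere_dir(double* d) {
  const double z = 2.0 * unif_rand() - 1.0;
  const double phi = 2.0 * M_PI * unif_rand();
  const double r = std::sqrt(std::max(0.0, 1.0 - z * z));
  d[0] = r * std::cos(phi);
  d[1] = r * std::sin(phi);
  d[2] = z;
}

// Uniform draw in the spherical cap of half-angle theta around axis u.
inline void cone_dir(const double* u, double cos_tmax, double* d) {
  const double z = 1.0 - unif_rand() * (1.0 - cos_tmax);
  const double phi = 2.0 * M_PI * unif_rand();
  const double r = std::sqrt(std::max(0.0, 1.0 - z * z));
  // orthonormal frame (a, b, u)
  double a[3];
  if (std::fabs(u[0]) < 0.9) { a[0] = 1; a[1] = 0; a[2] = 0; }
  else { a[0] = 0; a[1] = 1; a[2] = 0; }
  double b[3] = {u[1] * a[2] - u[2] * a[1], u[2] * a[0] - u[0] * a[2],
                 u[0] * a[1] - u[1] * a[0]};
  double nb = std::sqrt(b[0] * b[0] + b[1] * b[1] + b[2] * b[2]);
  for (int k = 0; k < 3; ++k) b[k] /= nb;
  double c[3] = {u[1] * b[2] - u[2] * b[1], u[2] * b[0] - u[0] * b[2],
                 u[0] * b[1] - u[1] * b[0]};
  const double ca = std::cos(phi), sa = std::sin(phi);
  for (int k = 0; k < 3; ++k)
    d[k] = r * (ca * b[k] + sa * c[k]) + z * u[k];
}

// Status codes shared with the R layer.
enum Term { OK = 0, TARGET = 1, MASK_EXIT = 2, LOW_AMP = 3, ANGLE_FAIL = 4,
            MAX_LEN = 5 };

// Rejection-sample one direction at a position. prev == NULL at seeding.
// Returns OK / LOW_AMP / ANGLE_FAIL; direction written to out.
int sample_dir(const Field& f, int lmax, const double* pos, const double* prev,
               double cos_tmax, double thresh, int max_attempts, int n_probe,
               double env_factor, double* coefbuf, double* shbuf, double* out) {
  interp_coefs(f, pos, coefbuf);
  // envelope from probe directions (times a safety factor)
  double env = 0.0;
  double d[3];
  for (int i = 0; i < n_probe; ++i) {
    if (prev) cone_dir(prev, cos_tmax, d); else unit_sphere_dir(d);
    const double a = trsh::amplitude(d, coefbuf, lmax, shbuf);
    if (a > env) env = a;
  }
  env *= env_factor;
  double best = env / env_factor;
  if (env <= 0.0) return LOW_AMP;
  for (int i = 0; i < max_attempts; ++i) {
    if (prev) cone_dir(prev, cos_tmax, d); else unit_sphere_dir(d);
    const double a = trsh::amplitude(d, coefbuf, lmax, shbuf);
    if (a > best) best = a;
    if (a < thresh) continue;
    if (unif_rand() * env < a) {
      out[0] = d[0]; out[1] = d[1]; out[2] = d[2];
      return OK;
    }
  }
  return best < thresh ? LOW_AMP : ANGLE_FAIL;
}

}  // namespace

// phase 0: sample the initial direction at the seed and grow the forward
// half-track along +d0; phase 1: grow the backward half-track along -d0
// (d0 supplied).  Split so the two halves can run on independent RNG
// substreams: proximal truncation of one half then cannot desynchronize
// the other, which keeps proximal tracks exact prefixes of extended ones.
// [[Rcpp::export(name = ".propagate_half_cpp")]]
List propagate_half_cpp(NumericVector coef, IntegerVector dims,
                        IntegerVector brain_mask, IntegerVector target_mask,
                        NumericMatrix world_to_vox, int lmax,
                        NumericVector seed, int phase, NumericVector d0_in,
                        double step, double theta_max, double fod_threshold,
                        int max_steps_per_half, int mode, int max_attempts,
                        int n_probe, double env_factor) {
  Field f;
  f.coef = coef.begin();
  f.brain = brain_mask.begin();
  f.target = target_mask.begin();
  f.nx = dims[0]; f.ny = dims[1]; f.nz = dims[2]; f.nc = dims[3];
  f.w2v = world_to_vox.begin();

  std::vector<double> coefbuf(f.nc), shbuf(f.nc);
  const double cos_tmax = std::cos(theta_max);
  const double s0[3] = {seed[0], seed[1], seed[2]};

  double d0[3];
  int term = LOW_AMP;
  bool hit = false;
  std::vector<double> half_pts;

  int st = OK;
  if (phase == 0) {
    st = sample_dir(f, lmax, s0, nullptr, cos_tmax, fod_threshold,
                    max_attempts, 2 * n_probe, env_factor, coefbuf.data(),
                    shbuf.data(), d0);
  } else {
    d0[0] = -d0_in[0]; d0[1] = -d0_in[1]; d0[2] = -d0_in[2];
  }
  if (st == OK) {
    double pos[3] = {s0[0], s0[1], s0[2]};
    double dir[3] = {d0[0], d0[1], d0[2]};
    bool first = true;
    term = MAX_LEN;
    for (int k = 0; k < max_steps_per_half; ++k) {
      if (!first) {
        double prev[3] = {dir[0], dir[1], dir[2]};
        int s = sample_dir(f, lmax, pos, prev, cos_tmax, fod_threshold,
                           max_attempts, n_probe, env_factor, coefbuf.data(),
                           shbuf.data(), dir);
        if (s != OK) { term = s; break; }
      }
      first = false;
      double npos[3] = {pos[0] + step * dir[0], pos[1] + step * dir[1],
                        pos[2] + step * dir[2]};
      // scan the segment at sub-step resolution so thin masks are not
      // stepped over (step << voxel size makes 4 probes sufficient)
      bool exited = false, entered_target = false;
      for (int q = 1; q <= 4; ++q) {
        const double t = 0.25 * q;
        double pq[3] = {pos[0] + t * step * dir[0],
                        pos[1] + t * step * dir[1],
                        pos[2] + t * step * dir[2]};
        if (!in_brain(f, pq)) { exited = true; break; }
        if (mode != 2 && target_at(f, pq) > 0) entered_target = true;
      }
      if (exited) { term = MASK_EXIT; break; }
      half_pts.push_back(npos[0]);
      half_pts.push_back(npos[1]);
      half_pts.push_back(npos[2]);
      pos[0] = npos[0]; pos[1] = npos[1]; pos[2] = npos[2];
      if (entered_target) {
        hit = true;
        if (mode == 0) { term = TARGET; break; }  // proximal truncation
      }
    }
  } else {
    term = st;
  }

  const int n1 = (int)half_pts.size() / 3;
  NumericMatrix pts(n1, 3);
  for (int i = 0; i < n1; ++i)
    for (int c = 0; c < 3; ++c) pts(i, c) = half_pts[3 * i + c];

  return List::create(_["points"] = pts, _["term"] = term, _["hit"] = hit,
                      _["d0"] = NumericVector::create(d0[0], d0[1], d0[2]),
                      _["ok"] = st == OK);
}
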