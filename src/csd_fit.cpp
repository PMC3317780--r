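// Constrained spherical deconvolution inner solver.
//
// Per voxel: minimize ||F x - s||^2 + ridge ||x||^2 subject to
// non-negativity of the FOD amplitude (A x >= 0) on a constraint set that
// grows by the tau rule (directions whose current amplitude falls below
// tau = tau_frac * mean initial amplitude).  The inequality-constrained
// problem is solved with a log-barrier interior-point method from a
// strictly feasible isotropic start, so returned FODs are non-negative on
// the constraint set by construction.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

namespace {

// barrier objective: x'Qx/2 - f'x - mu * sum(log(Ac x))
double barrier_obj(const mat& Q, const vec& f, const mat& Ac, const vec& x,
                   double mu) {
  vec a = Ac * x;
  if (a.min() <= 0) return datum::inf;
  return 0.5 * dot(x, Q * x) - dot(f, x) - mu * accu(log(a));
}

// log-barrier interior-point solve of
//   min x'Qx/2 - f'x  s.t.  Ac x >= 0,
// starting from a strictly feasible x (all amplitudes > 0).  Iterates stay
// strictly feasible, so the returned FOD is non-negative on the constraint
// set by construction.
bool qp_nonneg(const mat& Q, const vec& f, const mat& Ac, const vec& x_feas,
               vec& x) {
  x = x_feas;
  vec a = Ac * x;
  if (a.min() <= 0) return false;
  double mu = 0.05 * (norm(f, 1) + 1e-12) / accu(1.0 / a);
  const double mu_end = 1e-9 * mu + 1e-300;
  const double dec_tol = 1e-10 * (norm(f, 2) + 1e-12);
  while (mu > mu_end) {
    for (int it = 0; it < 25; ++it) {
      a = Ac * x;
      vec ia = 1.0 / a;
      vec grad = Q * x - f - mu * (Ac.t() * ia);
      mat H = Q + mu * (Ac.t() * (Ac.each_col() % (ia % ia)));
      vec dx;
      if (!solve(dx, H, -grad, solve_opts::likely_sympd)) return false;
      if (-dot(grad, dx) < dec_tol) break;  // Newton decrement
      // keep strictly inside the feasible cone
      vec ad = Ac * dx;
      double tmax = 1.0;
      for (uword i = 0; i < a.n_elem; ++i)
        if (ad(i) < 0) tmax = std::min(tmax, -0.99 * a(i) / ad(i));
      double f0 = barrier_obj(Q, f, Ac, x, mu);
      double t = tmax;
      int bt = 0;
      while (bt < 30 && barrier_obj(Q, f, Ac, x + t * dx, mu) > f0) {
        t *= 0.5;
        ++bt;
      }
      if (bt >= 30) break;
      x += t * dx;
      if (norm(t * dx, "inf") < 1e-12 * (norm(x, "inf") + 1e-12)) break;
    }
    mu *= 0.1;
  }
  return true;
}

}  // namespace

// [[Rcpp::export(name = ".csd_solve_cpp")]]
Rcpp::List csd_solve_cpp(const arma::mat& FWD, const arma::mat& S,
                         const arma::mat& A, double tau_frac,
                         double ridge_frac, int max_outer) {
  const uword nc = FWD.n_cols;
  const uword nvox = S.n_cols;
  mat FtF = FWD.t() * FWD;
  const double ridge = ridge_frac * trace(FtF) / nc;
  mat Q = FtF + ridge * eye(nc, nc);
  mat Qchol = chol(Q);
  mat coeffs(nc, nvox, fill::zeros);
  Rcpp::LogicalVector nonconv(nvox);

  for (uword v = 0; v < nvox; ++v) {
    vec s = S.col(v);
    vec f = FWD.t() * s;
    vec x0 = solve(trimatl(Qchol.t()), f);
    x0 = solve(trimatu(Qchol), x0);
    vec amp0 = A * x0;
    const double tau = tau_frac * mean(amp0);
    // strictly feasible interior start: isotropic FOD at the mean amplitude
    vec x_feas(nc, fill::zeros);
    x_feas(0) = std::max(mean(amp0), 0.01 * abs(amp0).max() + 1e-12) /
                A(0, 0);
    vec x = x0;
    std::vector<bool> in_cset(A.n_rows, false);
    uvec cset;
    bool converged = false;
    for (int it = 0; it < max_outer; ++it) {
      vec amp = A * x;
      uword added = 0;
      for (uword i = 0; i < A.n_rows; ++i) {
        if (!in_cset[i] && amp(i) < tau) {
          in_cset[i] = true;
          ++added;
        }
      }
      if (added == 0) { converged = true; break; }
      std::vector<uword> tmp;
      for (uword i = 0; i < A.n_rows; ++i)
        if (in_cset[i]) tmp.push_back(i);
      cset = uvec(tmp);
      vec xs;
      if (!qp_nonneg(Q, f, A.rows(cset), x_feas, xs)) break;
      x = xs;
    }
    coeffs.col(v) = x;
    nonconv(v) = !converged;
  }
  return Rcpp::List::create(Rcpp::_["coeffs"] = coeffs,
                            Rcpp::_["nonconverged"] = nonconv);
}
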