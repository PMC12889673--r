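// Fixed-point solver for rectified rate networks: explicit Euler on
// tau dr/dt = -r + f(W r + h) with a damped Newton polish near the
// solution. Hot path of the fitter, hence compiled.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static vec apply_nl(const vec& u, const int kind) {
  vec up = clamp(u, 0.0, datum::inf);
  if (kind == 0) return up % up;   // rectified quadratic
  return up;                        // rectified linear
}

static vec nl_deriv(const vec& u, const int kind) {
  if (kind == 0) return 2.0 * clamp(u, 0.0, datum::inf);
  return conv_to<vec>::from(u > 0);
}

// [[Rcpp::export(name = ".fixed_point_cpp")]]
Rcpp::List fixed_point_cpp(const arma::mat& W, const arma::vec& h,
                           const arma::vec& tau, const int nl_kind,
                           const arma::vec& r0, const double dt,
                           const double tol, const int max_steps,
                           const double ceiling, const bool accelerate) {
  const uword m = W.n_rows;
  vec step = dt / tau;
  vec r = r0;
  double res = datum::inf;
  double res_hist = datum::inf;
  int hist_k = 0;
  int newton_block = 0;

  for (int k = 1; k <= max_steps; ++k) {
    vec u = W * r + h;
    vec fu = apply_nl(u, nl_kind);
    vec dr = fu - r;

    if (k % 10 == 0 || k == 1) {
      res = abs(dr).max() / (r.max() + 1e-12);
      if (res < tol) {
        return Rcpp::List::create(
          Rcpp::Named("rates") = r, Rcpp::Named("converged") = true,
          Rcpp::Named("diverged") = false, Rcpp::Named("steps") = k,
          Rcpp::Named("residual") = res);
      }
      if (accelerate && res < 1e-2 && k > newton_block) {
        // damped Newton polish on g(r) = f(Wr+h) - r; the Jacobian
        // factorization is frozen (chord method) and refreshed only when
        // progress stalls
        vec rn = r, un = u, fn = fu;
        double best = res;
        bool ok = false;
        double res_n = res;
        mat LU_L, LU_U, LU_P;
        bool have_fac = false;
        int refreshes = 0;
        for (int it = 0; it < 40; ++it) {
          vec g = fn - rn;
          if (!have_fac) {
            mat A = -(diagmat(nl_deriv(un, nl_kind)) * W);
            A.diag() += 1.0;
            if (!lu(LU_L, LU_U, LU_P, A)) break;
            have_fac = true;
          }
          vec drn = solve(trimatu(LU_U),
                          solve(trimatl(LU_L), LU_P * g,
                                solve_opts::fast),
                          solve_opts::fast);
          if (!drn.is_finite()) break;
          vec rtry = rn + drn;
          if (!rtry.is_finite() || rtry.max() > ceiling) break;
          un = W * rtry + h;
          fn = apply_nl(un, nl_kind);
          res_n = abs(fn - rtry).max() / (rtry.max() + 1e-12);
          if (!std::isfinite(res_n)) break;
          if (res_n < tol) { rn = rtry; ok = true; break; }
          if (res_n > 0.7 * best) {
            if (refreshes++ >= 2) break;
            have_fac = false;        // stale Jacobian: refresh once
            if (res_n < best) { rn = rtry; best = res_n; }
            continue;
          }
          rn = rtry;
          best = res_n;
        }
        if (ok) {
          return Rcpp::List::create(
            Rcpp::Named("rates") = rn, Rcpp::Named("converged") = true,
            Rcpp::Named("diverged") = false, Rcpp::Named("steps") = k,
            Rcpp::Named("residual") = res_n);
        }
        newton_block = k + 200;
      }
      // stalled oscillation far from a fixed point: give up early
      if (k - hist_k >= 400) {
        if (res > std::max(100.0 * tol, 1e-3) && res > 0.95 * res_hist) {
          return Rcpp::List::create(
            Rcpp::Named("rates") = r, Rcpp::Named("converged") = false,
            Rcpp::Named("diverged") = false, Rcpp::Named("steps") = k,
            Rcpp::Named("residual") = res);
        }
        res_hist = res;
        hist_k = k;
      }
    }

    r += step % dr;
    if (!r.is_finite() || r.max() > ceiling) {
      return Rcpp::List::create(
        Rcpp::Named("rates") = r, Rcpp::Named("converged") = false,
        Rcpp::Named("diverged") = true, Rcpp::Named("steps") = k,
        Rcpp::Named("residual") = datum::inf);
    }
  }
  vec u = W * r + h;
  vec fu = apply_nl(u, nl_kind);
  res = abs(fu - r).max() / (r.max() + 1e-12);
  bool conv = res < tol;
  return Rcpp::List::create(
    Rcpp::Named("rates") = r, Rcpp::Named("converged") = conv,
    Rcpp::Named("diverged") = false, Rcpp::Named("steps") = max_steps,
    Rcpp::Named("residual") = res);
}
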