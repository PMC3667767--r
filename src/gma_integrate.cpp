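// Fixed-step RK4 integration of GMA (product of power-law) ODE systems with
// piecewise-constant independent variables. This is the hot path inside the
// per-interval optimizer; the user-facing simulator uses deSolve::lsoda.
//
// Flux vector: v = exp(log_gamma + offset + KOd %*% log(y_clipped)), where
// `offset` collects the (constant within an interval) contribution of the
// independent variables, KOi %*% log(indep).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double GMA_FLOOR = 1e-12;

static inline vec gma_rhs(const vec& y, const mat& KOd, const mat& S,
                          const vec& lg_off) {
  vec yc = clamp(y, GMA_FLOOR, datum::inf);
  vec v = exp(lg_off + KOd * log(yc));
  return S * v;
}

static vec rk4_span(vec y, const mat& KOd, const mat& S, const vec& lg_off,
                    double dt, int nstep) {
  const double h = dt / nstep;
  for (int i = 0; i < nstep; ++i) {
    vec k1 = gma_rhs(y, KOd, S, lg_off);
    vec k2 = gma_rhs(y + 0.5 * h * k1, KOd, S, lg_off);
    vec k3 = gma_rhs(y + 0.5 * h * k2, KOd, S, lg_off);
    vec k4 = gma_rhs(y + h * k3, KOd, S, lg_off);
    y += (h / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
  }
  return y;
}

// Integrate one interval of length dt; returns the final dependent state.
// [[Rcpp::export]]
arma::vec cpp_gma_step(const arma::vec& y0, const arma::mat& KOd,
                       const arma::mat& S, const arma::vec& lg_off,
                       double dt, int nstep) {
  return rk4_span(y0, KOd, S, lg_off, dt, nstep);
}

// Piecewise integration over consecutive unit intervals. `lg_off` has one
// column per interval (log_gamma + KOi %*% log(indep) for that interval).
// Returns the trajectory at interval boundaries: (n_int + 1) x n_dep.
// [[Rcpp::export]]
arma::mat cpp_gma_piecewise(const arma::vec& y0, const arma::mat& KOd,
                            const arma::mat& S, const arma::mat& lg_off,
                            double dt, int nstep) {
  const uword n_int = lg_off.n_cols;
  mat out(n_int + 1, y0.n_elem);
  vec y = y0;
  out.row(0) = y.t();
  for (uword j = 0; j < n_int; ++j) {
    y = rk4_span(y, KOd, S, lg_off.col(j), dt, nstep);
    out.row(j + 1) = y.t();
  }
  return out;
}
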