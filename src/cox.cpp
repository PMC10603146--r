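// Cox partial-likelihood machinery (Breslow ties throughout).
//
// All routines work on a fixed ordering of subjects by decreasing observed
// time, with tied times handled as blocks: the risk set at an event time t
// is every subject with T >= t, so cumulative sums are snapshotted at the
// end of each tie block.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct CoxOrder {
  arma::uvec ord;        // indices sorted by decreasing time
  arma::vec time_o;      // time in that order
  arma::vec status_o;    // status in that order
  arma::uvec block_end;  // for each position, last position of its tie block
};

CoxOrder cox_order(const arma::vec& time, const arma::vec& status) {
  CoxOrder co;
  co.ord = arma::stable_sort_index(time, "descend");
  const arma::uword n = time.n_elem;
  co.time_o.set_size(n);
  co.status_o.set_size(n);
  for (arma::uword i = 0; i < n; ++i) {
    co.time_o(i) = time(co.ord(i));
    co.status_o(i) = status(co.ord(i));
  }
  co.block_end.set_size(n);
  arma::uword i = 0;
  while (i < n) {
    arma::uword j = i;
    while (j + 1 < n && co.time_o(j + 1) == co.time_o(i)) ++j;
    for (arma::uword k = i; k <= j; ++k) co.block_end(k) = j;
    i = j + 1;
  }
  return co;
}

// Breslow partial log-likelihood from a linear predictor, with
// log-sum-exp stabilisation.
double pl_from_eta(const arma::vec& eta, const CoxOrder& co) {
  const arma::uword n = eta.n_elem;
  const double m = eta.max();
  arma::vec eta_o(n), w(n);
  for (arma::uword i = 0; i < n; ++i) {
    eta_o(i) = eta(co.ord(i));
    w(i) = std::exp(eta_o(i) - m);
  }
  double pl = 0.0, s0 = 0.0;
  arma::uword i = 0;
  while (i < n) {
    const arma::uword be = co.block_end(i);
    for (arma::uword k = i; k <= be; ++k) s0 += w(k);
    const double log_s0 = std::log(s0) + m;
    for (arma::uword k = i; k <= be; ++k)
      if (co.status_o(k) == 1.0) pl += eta_o(k) - log_s0;
    i = be + 1;
  }
  return pl;
}

}  // namespace

//' @noRd
// [[Rcpp::export]]
double cpp_cox_pl(const arma::vec& eta, const arma::vec& time,
                  const arma::vec& status) {
  CoxOrder co = cox_order(time, status);
  return pl_from_eta(eta, co);
}

// Per-subject first derivative u_i = d pl / d eta_i and the (positive)
// diagonal of the negative second derivative, plus pl itself.
// u_i = delta_i - exp(eta_i) * sum_{event times t <= T_i} d_t / S0(t)
// h_i = exp(eta_i) * G1_i - exp(2 eta_i) * G2_i,  G2 using S0(t)^2.
// [[Rcpp::export]]
List cpp_cox_eta_derivs(const arma::vec& eta, const arma::vec& time,
                        const arma::vec& status) {
  CoxOrder co = cox_order(time, status);
  const arma::uword n = eta.n_elem;
  const double m = eta.max();
  arma::vec w(n), eta_o(n);
  for (arma::uword i = 0; i < n; ++i) {
    eta_o(i) = eta(co.ord(i));
    w(i) = std::exp(eta_o(i) - m);
  }
  // S0 over the risk set at each tie block (descending pass).
  arma::vec s0_block(n, arma::fill::zeros);
  double s0 = 0.0;
  {
    arma::uword i = 0;
    while (i < n) {
      const arma::uword be = co.block_end(i);
      for (arma::uword k = i; k <= be; ++k) s0 += w(k);
      for (arma::uword k = i; k <= be; ++k) s0_block(k) = s0;  // scaled by e^-m
      i = be + 1;
    }
  }
  // Ascending pass accumulating event-time sums G1, G2.
  arma::vec u(n), h(n);
  double g1 = 0.0, g2 = 0.0;
  {
    arma::sword i = static_cast<arma::sword>(n) - 1;
    while (i >= 0) {
      arma::sword bs = i;  // block start (ascending): find first of tie block
      while (bs > 0 && co.time_o(bs - 1) == co.time_o(i)) --bs;
      double d_t = 0.0;
      for (arma::sword k = bs; k <= i; ++k) d_t += co.status_o(k);
      if (d_t > 0.0) {
        g1 += d_t / s0_block(i);
        g2 += d_t / (s0_block(i) * s0_block(i));
      }
      for (arma::sword k = bs; k <= i; ++k) {
        const double ew = w(k);  // exp(eta - m)
        const double mu = ew * g1;  // e^-m cancels: ew * (d/S0*e^-m scale)
        u(co.ord(k)) = co.status_o(k) - mu;
        h(co.ord(k)) = mu - ew * ew * g2;
      }
      i = bs - 1;
    }
  }
  return List::create(_["u"] = u, _["h"] = h,
                      _["pl"] = pl_from_eta(eta, co));
}

// Full observed information (negative Hessian of pl) w.r.t. beta:
// sum over events of S2/S0 - (S1/S0)(S1/S0)^T over the risk set.
// [[Rcpp::export]]
arma::mat cpp_cox_info(const arma::mat& X, const arma::vec& eta,
                       const arma::vec& time, const arma::vec& status) {
  CoxOrder co = cox_order(time, status);
  const arma::uword n = X.n_rows, p = X.n_cols;
  const double m = eta.max();
  arma::mat H(p, p, arma::fill::zeros);
  arma::mat S2(p, p, arma::fill::zeros);
  arma::vec S1(p, arma::fill::zeros);
  double S0 = 0.0;
  arma::uword i = 0;
  while (i < n) {
    const arma::uword be = co.block_end(i);
    for (arma::uword k = i; k <= be; ++k) {
      const arma::uword idx = co.ord(k);
      const double w = std::exp(eta(idx) - m);
      const arma::vec x = X.row(idx).t();
      S0 += w;
      S1 += w * x;
      S2 += w * (x * x.t());
    }
    double d_t = 0.0;
    for (arma::uword k = i; k <= be; ++k) d_t += co.status_o(k);
    if (d_t > 0.0) {
      const arma::vec xbar = S1 / S0;
      H += d_t * (S2 / S0 - xbar * xbar.t());
    }
    i = be + 1;
  }
  return H;
}

// Newton maximisation of pl(beta) - 0.5 * beta' diag(d) beta with
// step-halving.  d = 0 gives the Cox MLE.
// [[Rcpp::export]]
List cpp_cox_newton(const arma::mat& X, const arma::vec& time,
                    const arma::vec& status, const arma::vec& ridge,
                    const arma::vec& beta_init, const double tol,
                    const int maxit) {
  CoxOrder co = cox_order(time, status);
  const arma::uword p = X.n_cols;
  arma::vec beta = beta_init;
  arma::vec eta = X * beta;
  double obj = pl_from_eta(eta, co) - 0.5 * arma::dot(ridge, beta % beta);
  bool converged = false, singular = false;
  int it = 0;
  arma::mat info(p, p, arma::fill::zeros);
  for (it = 0; it < maxit; ++it) {
    // score and information at current beta
    List d = cpp_cox_eta_derivs(eta, time, status);
    arma::vec u = d["u"];
    arma::vec g = X.t() * u - ridge % beta;
    info = cpp_cox_info(X, eta, time, status);
    arma::mat A = info;
    A.diag() += ridge;
    arma::vec step;
    bool ok = arma::solve(step, A, g, arma::solve_opts::no_approx);
    if (!ok || !step.is_finite()) { singular = true; break; }
    double alpha = 1.0;
    double new_obj = -arma::datum::inf;
    arma::vec beta_new, eta_new;
    for (int half = 0; half < 30; ++half) {
      beta_new = beta + alpha * step;
      eta_new = X * beta_new;
      new_obj = pl_from_eta(eta_new, co) -
                0.5 * arma::dot(ridge, beta_new % beta_new);
      if (std::isfinite(new_obj) && new_obj >= obj - 1e-12) break;
      alpha *= 0.5;
    }
    const double rel = std::fabs(new_obj - obj) /
                       (std::fabs(obj) + 1e-10);
    beta = beta_new;
    eta = eta_new;
    obj = new_obj;
    if (rel < tol) { converged = true; ++it; break; }
  }
  info = cpp_cox_info(X, eta, time, status);
  return List::create(_["beta"] = beta, _["pl"] = pl_from_eta(eta, co),
                      _["objective"] = obj, _["info"] = info,
                      _["ridge"] = ridge, _["iter"] = it,
                      _["converged"] = converged, _["singular"] = singular);
}

// Penalised coordinate descent for the Cox model:
//   minimise  -pl(beta) + sum_j w_j |beta_j| + 0.5 * sum_j d_j beta_j^2
// via iteratively reweighted least squares with the diagonal of the true
// Hessian, and cyclic soft-threshold updates (the glmnet scheme, on the
// unscaled -pl objective).
// [[Rcpp::export]]
List cpp_cox_cd(const arma::mat& X, const arma::vec& time,
                const arma::vec& status, const arma::vec& w,
                const arma::vec& d, const arma::vec& beta_init,
                const double tol, const int maxit_outer,
                const int maxit_inner) {
  CoxOrder co = cox_order(time, status);
  const arma::uword n = X.n_rows, p = X.n_cols;
  arma::vec beta = beta_init;
  arma::vec eta = X * beta;
  bool converged = false;
  int outer = 0;
  const double wmin = 1e-10;
  for (outer = 0; outer < maxit_outer; ++outer) {
    List dv = cpp_cox_eta_derivs(eta, time, status);
    arma::vec u = dv["u"];
    arma::vec h = dv["h"];
    for (arma::uword i = 0; i < n; ++i) if (h(i) < wmin) h(i) = wmin;
    // working residual r = z - X beta with z = eta + u/h
    arma::vec r = u / h;
    arma::vec xwx(p);
    for (arma::uword j = 0; j < p; ++j)
      xwx(j) = arma::dot(h, X.col(j) % X.col(j));
    arma::vec beta_old_outer = beta;
    // one coordinate update; returns |change|
    auto update_j = [&](arma::uword j) -> double {
      if (!std::isfinite(w(j))) {  // infinite L1 weight: excluded
        if (beta(j) != 0.0) {
          r += X.col(j) * beta(j);
          const double ch = std::fabs(beta(j));
          beta(j) = 0.0;
          return ch;
        }
        return 0.0;
      }
      const double num = arma::dot(h % X.col(j), r) + xwx(j) * beta(j);
      double bj;
      const double thr = w(j);
      if (num > thr) bj = (num - thr) / (xwx(j) + d(j));
      else if (num < -thr) bj = (num + thr) / (xwx(j) + d(j));
      else bj = 0.0;
      const double delta = bj - beta(j);
      if (delta != 0.0) {
        r -= X.col(j) * delta;
        beta(j) = bj;
      }
      return std::fabs(delta);
    };
    // active-set cycling: full sweep, then iterate over the nonzero set
    // until stable, then re-sweep to catch violations
    for (int inner = 0; inner < maxit_inner; ++inner) {
      double max_delta = 0.0;
      for (arma::uword j = 0; j < p; ++j)
        max_delta = std::max(max_delta, update_j(j));
      if (max_delta < 0.1 * tol) break;
      arma::uvec active = arma::find(beta != 0.0);
      for (int pass = 0; pass < maxit_inner; ++pass) {
        double md = 0.0;
        for (arma::uword k = 0; k < active.n_elem; ++k)
          md = std::max(md, update_j(active(k)));
        if (md < 0.1 * tol) break;
      }
    }
    eta = X * beta;
    const double outer_delta = arma::abs(beta - beta_old_outer).max();
    if (outer_delta < tol) { converged = true; ++outer; break; }
  }
  return List::create(_["beta"] = beta, _["pl"] = pl_from_eta(eta, co),
                      _["iter"] = outer, _["converged"] = converged);
}
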