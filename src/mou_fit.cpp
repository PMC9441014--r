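// Lyapunov gradient-descent core for fitting the MOU effective-connectivity
// model. Per iteration: one eigendecomposition of the Jacobian provides the
// stationary covariance (Lyapunov solution), the lagged covariance and the
// matrix exponentials used by the gradient, so the cost stays O(n^3).
// The iteration uses fixed learning rates (the update is a fixed-point
// heuristic, not a strict gradient, so the error may wobble locally while
// descending); the only rate control is a safeguard that reverts to the
// best iterate with a halved rate whenever a step destabilises the model.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

namespace {

struct CovState {
  mat Q0;      // stationary covariance
  mat Q1;      // lagged covariance Q0 * expm(J' * lag)
  mat EnegT;   // expm(-J' * lag)
  double err;  // normalised model error vs the empirical pair
  bool ok;
};

// Covariances of the MOU model with Jacobian J and diagonal noise sigma,
// via J = V diag(lambda) V^{-1}.
CovState model_cov(const mat& J, const vec& sigma, double lag_s,
                   const mat& q0emp, const mat& q1emp, double denom,
                   bool need_grad) {
  CovState st;
  st.ok = false;
  st.err = datum::inf;
  cx_vec lam;
  cx_mat V;
  if (!eig_gen(lam, V, J)) return st;
  if (lam.n_elem == 0 || max(real(lam)) >= 0) return st;
  cx_mat Vi;
  if (!inv(Vi, V)) return st;
  cx_mat S = Vi * diagmat(conv_to<cx_vec>::from(sigma)) * Vi.st();
  cx_mat M(S.n_rows, S.n_cols);
  for (uword i = 0; i < S.n_rows; ++i)
    for (uword j = 0; j < S.n_cols; ++j)
      M(i, j) = -S(i, j) / (lam(i) + lam(j));
  mat Q0 = real(V * M * V.st());
  st.Q0 = 0.5 * (Q0 + Q0.t());
  mat E = real(V * diagmat(exp(lam * lag_s)) * Vi);      // expm(J * lag)
  st.Q1 = st.Q0 * E.t();                                  // expm(J' lag) = E'
  st.err = (accu(square(q0emp - st.Q0)) + accu(square(q1emp - st.Q1))) / denom;
  if (!std::isfinite(st.err)) return st;
  if (need_grad) {
    mat Eneg = real(V * diagmat(exp(-lam * lag_s)) * Vi); // expm(-J * lag)
    st.EnegT = Eneg.t();
  }
  st.ok = true;
  return st;
}

mat jacobian(const mat& ec, double tau) {
  mat J = ec.t();
  J.diag().fill(-1.0 / tau);
  return J;
}

double pearson(const vec& a, const vec& b) {
  double sa = stddev(a), sb = stddev(b);
  if (sa == 0 || sb == 0) return NA_REAL;
  return as_scalar(cor(a, b));
}

vec fit_vector(const mat& Q0, const mat& Q1) {
  uword n = Q0.n_rows;
  std::vector<double> v;
  v.reserve(n * (n + 1) / 2 + n * n);
  for (uword j = 0; j < n; ++j)
    for (uword i = j; i < n; ++i) v.push_back(Q0(i, j));
  for (uword j = 0; j < n; ++j)
    for (uword i = 0; i < n; ++i) v.push_back(Q1(i, j));
  return vec(v);
}

}  // namespace

// [[Rcpp::export(name = ".mou_fit_core")]]
Rcpp::List mou_fit_core(const arma::mat& q0emp, const arma::mat& q1emp,
                        const arma::mat& mask, double tau, double lag_s,
                        const arma::vec& sigma_init,
                        double rate_ec, double rate_sigma, double sigma_floor,
                        int max_iter, int patience) {
  const uword n = q0emp.n_rows;
  const double denom = accu(square(q0emp)) + accu(square(q1emp));
  const vec v_emp = fit_vector(q0emp, q1emp);

  mat ec(n, n, fill::zeros);
  vec sigma = sigma_init;
  double best_err = datum::inf;
  mat best_ec = ec;
  vec best_sigma = sigma;
  int best_iter = 0;
  int since_best = 0;
  int diverge_run = 0;
  double err0 = -1.0;
  double cur_rate = 1.0;  // multiplier on (rate_ec, rate_sigma)
  bool pinv_used = false, diverged = false, converged = false;
  std::vector<double> err_hist;
  err_hist.reserve(max_iter);
  double best_r = -2.0;

  int it = 0;
  for (; it < max_iter; ++it) {
    mat J = jacobian(ec, tau);
    CovState st = model_cov(J, sigma, lag_s, q0emp, q1emp, denom, true);
    if (!st.ok) {
      // the last update destabilised the model: back off to the best
      // iterate with a halved rate
      ec = best_ec;
      sigma = best_sigma;
      cur_rate *= 0.5;
      if (cur_rate < 1e-9) break;
      continue;
    }
    err_hist.push_back(st.err);
    if (err0 < 0) err0 = st.err;
    if (st.err > std::max(10.0 * err0, 2.0 * best_err)) {
      // blow-up beyond the trust region: back off to the best iterate and anneal
      ec = best_ec;
      sigma = best_sigma;
      cur_rate *= 0.5;
      if (++diverge_run >= 100) { diverged = true; break; }
      if (cur_rate < 1e-9) break;
      continue;
    }
    double r = pearson(fit_vector(st.Q0, st.Q1), v_emp);
    if (std::isfinite(r) && r > best_r) best_r = r;
    if (st.err < best_err) {
      best_err = st.err;
      best_ec = ec;
      best_sigma = sigma;
      best_iter = it;
      since_best = 0;
    } else if (++since_best > patience) {
      converged = true;
      break;
    }
    mat dq0 = q0emp - st.Q0;
    mat dq1 = q1emp - st.Q1;
    mat rhs = dq0 + dq1.t() * st.EnegT;
    mat dJt;
    if (!solve(dJt, st.Q0, rhs, solve_opts::no_approx)) {
      dJt = pinv(st.Q0) * rhs;
      pinv_used = true;
    }
    ec += (cur_rate * rate_ec) * (dJt.t() % mask);   // DJ restricted to mask
    ec.clamp(0.0, datum::inf);
    sigma += (cur_rate * rate_sigma) * diagvec(-J.t() * dq0 - dq0 * J);
    sigma.clamp(sigma_floor, datum::inf);
  }

  return Rcpp::List::create(
      Rcpp::Named("ec") = best_ec,
      Rcpp::Named("sigma") = best_sigma,
      Rcpp::Named("error_history") = err_hist,
      Rcpp::Named("best_error") = best_err,
      Rcpp::Named("best_iter") = best_iter,
      Rcpp::Named("best_pearson_r") = best_r,
      Rcpp::Named("iterations") = (int)err_hist.size(),
      Rcpp::Named("converged") = converged,
      Rcpp::Named("diverged") = diverged,
      Rcpp::Named("pinv_used") = pinv_used);
}
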