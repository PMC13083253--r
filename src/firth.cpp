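#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Penalized (Jeffreys-prior) log-likelihood and ingredients at beta.
// Observation weights w_obs allow collapsed designs with replicated rows.
static bool firth_eval(const mat& X, const vec& y, const vec& w_obs,
                       const vec& beta, double& loglik, vec& pi_hat,
                       vec& h, mat& XtWX) {
  vec eta = X * beta;
  eta = clamp(eta, -30.0, 30.0);
  pi_hat = 1.0 / (1.0 + exp(-eta));
  vec w = w_obs % pi_hat % (1.0 - pi_hat);
  mat Xw = X.each_col() % sqrt(w);
  XtWX = Xw.t() * Xw;
  double ld, sign;
  if (!log_det(ld, sign, XtWX) || sign <= 0.0) return false;
  mat XtWXinv;
  if (!inv_sympd(XtWXinv, XtWX)) return false;
  h = sum((Xw * XtWXinv) % Xw, 1);
  loglik = accu(w_obs % (y % log(pi_hat) + (1.0 - y) % log(1.0 - pi_hat)))
         + 0.5 * ld;
  return true;
}

// Firth logistic regression by modified-score Newton iteration with
// step-halving. Coefficients not in free_idx are held fixed at beta_init
// (the penalty always uses the full-design information matrix, so the
// same routine serves full fits, profile-likelihood refits and the
// constrained fits behind the penalized LRT).
// [[Rcpp::export]]
Rcpp::List firth_fit_engine(const arma::mat& X, const arma::vec& y,
                            const arma::vec& w_obs,
                            const arma::uvec& free_idx,
                            const arma::vec& beta_init,
                            int max_iter, double tol,
                            int max_halving, double max_step) {
  vec beta = beta_init;
  double loglik;
  vec pi_hat, h;
  mat XtWX;
  if (!firth_eval(X, y, w_obs, beta, loglik, pi_hat, h, XtWX))
    Rcpp::stop("information matrix is singular at the starting values");

  bool converged = false;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    // modified score: weighted data term plus the leverage correction of
    // the collapsed row (the correction is not replicated by w_obs)
    vec resid = w_obs % (y - pi_hat) + h % (0.5 - pi_hat);
    vec score_full = X.t() * resid;
    vec score = score_full(free_idx);
    if (free_idx.n_elem == 0 || norm(score, "inf") < tol) {
      converged = true;
      break;
    }
    mat I_free = XtWX(free_idx, free_idx);
    vec delta;
    if (!solve(delta, I_free, score, solve_opts::likely_sympd))
      Rcpp::stop("singular information matrix during iteration");
    double mx = norm(delta, "inf");
    if (mx > max_step) delta *= max_step / mx;

    double loglik_new;
    vec pi_new, h_new;
    mat XtWX_new;
    vec beta_new = beta;
    bool ok = false;
    for (int half = 0; half <= max_halving; ++half) {
      beta_new = beta;
      beta_new(free_idx) += delta;
      if (firth_eval(X, y, w_obs, beta_new, loglik_new, pi_new, h_new,
                     XtWX_new) && loglik_new >= loglik - 1e-10) {
        ok = true;
        break;
      }
      delta *= 0.5;
    }
    if (!ok) break;  // no admissible step; convergence judged on score
    beta = beta_new;
    loglik = loglik_new;
    pi_hat = pi_new;
    h = h_new;
    XtWX = XtWX_new;
  }

  mat XtWXinv;
  vec se(beta.n_elem);
  se.fill(datum::nan);
  if (inv_sympd(XtWXinv, XtWX)) se = sqrt(XtWXinv.diag());

  return Rcpp::List::create(
    Rcpp::Named("beta") = beta,
    Rcpp::Named("se") = se,
    Rcpp::Named("hat") = h,
    Rcpp::Named("loglik_pen") = loglik,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("n_iter") = iter);
}
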