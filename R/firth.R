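#' @useDynLib urvscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pchisq qchisq qnorm pnorm rbinom rnorm rpois runif rexp
#'   median lm coef vcov fisher.test rhyper plogis qlogis rgeom complete.cases
#'   setNames mad rmultinom
NULL

.validate_design <- function(X, y) {
  if (!is.matrix(X)) X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) == 0L || ncol(X) == 0L) stop("empty design matrix")
  if (anyNA(X) || anyNA(y)) stop("design matrix and response must not contain missing values")
  if (!all(y %in% c(0, 1))) stop("response must be coded 0/1")
  if (sum(y == 1) == 0L || sum(y == 0) == 0L)
    stop("response needs at least one case and one control")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  const <- which(apply(X, 2, function(v) length(unique(v)) == 1L))
  const <- setdiff(const, c(1L, which(colnames(X) == "(Intercept)")))
  if (length(const))
    stop("constant column: ", paste(colnames(X)[const], collapse = ", "))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear columns: ", paste(bad, collapse = ", "))
  }
  X
}

#' Firth bias-reduced logistic regression
#'
#' Maximizes the Jeffreys-prior penalized log-likelihood
#' \eqn{l^*(\beta) = l(\beta) + \tfrac12 \log\det I(\beta)} by modified-score
#' Newton iteration with step-halving. Estimates are finite even under
#' complete separation, and penalized likelihood-ratio tests on rare
#' predictors remain calibrated in heavily unbalanced case-control designs,
#' which is why this engine backs every association test in the package.
#'
#' @param X numeric design matrix (include an intercept column explicitly).
#' @param y binary response vector (0/1), one element per row of `X`.
#' @param max_iter maximum number of Newton iterations.
#' @param tol convergence tolerance on the maximum absolute modified score.
#' @param weights optional nonnegative observation weights (replicate counts
#'   for collapsed designs).
#' @param beta_init optional starting values.
#' @param free integer indices of coefficients to estimate; the remaining
#'   coefficients are held at `beta_init` (used internally for profile and
#'   constrained fits).
#' @return an object of class `firth_fit`: list with `beta`, `se`, `hat`
#'   (per-observation leverages), `loglik_pen`, `converged`, `n_iter`.
#' @examples
#' X <- cbind(1, c(rep(0, 5), rep(1, 5)))
#' y <- c(0, 0, 0, 0, 1, 0, 1, 1, 1, 1)
#' fit_firth(X, y)$beta
#' @export
fit_firth <- function(X, y, max_iter = 100L, tol = 1e-8, weights = NULL,
                      beta_init = NULL, free = NULL) {
  X <- .validate_design(X, y)
  stopifnot(max_iter >= 1L, tol > 0)
  n <- nrow(X); p <- ncol(X)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (is.null(beta_init)) {
    beta_init <- numeric(p)
    ybar <- sum(weights * y) / sum(weights)
    beta_init[1L] <- qlogis((sum(weights * y) + 0.5) / (sum(weights) + 1))
    if (!all(X[, 1L] == 1)) beta_init[1L] <- 0
  }
  if (is.null(free)) free <- seq_len(p)
  res <- firth_fit_engine(X, as.numeric(y), as.numeric(weights),
                          as.integer(free) - 1L, as.numeric(beta_init),
                          as.integer(max_iter), tol, 25L, 5.0)
  fit <- list(beta = setNames(drop(res$beta), colnames(X)),
              se = setNames(drop(res$se), colnames(X)),
              hat = drop(res$hat),
              loglik_pen = res$loglik_pen,
              converged = res$converged,
              n_iter = res$n_iter,
              n = n)
  class(fit) <- "firth_fit"
  fit
}

#' @export
print.firth_fit <- function(x, ...) {
  cat("Firth penalized logistic fit (", x$n, " obs, ",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$n_iter, " iterations)\n", sep = "")
  print(cbind(beta = x$beta, se = x$se))
  cat("penalized log-likelihood:", format(x$loglik_pen), "\n")
  invisible(x)
}

.profile_loglik <- function(X, y, weights, index, value, beta_start,
                            max_iter = 100L, tol = 1e-8) {
  p <- ncol(X)
  beta_start[index] <- value
  free <- setdiff(seq_len(p), index)
  res <- firth_fit_engine(X, as.numeric(y), as.numeric(weights),
                          as.integer(free) - 1L, as.numeric(beta_start),
                          as.integer(max_iter), tol, 25L, 5.0)
  if (!res$converged && length(free) > 0L)
    stop("profile refit did not converge at beta = ", format(value))
  list(loglik = res$loglik_pen, beta = drop(res$beta))
}

#' Profile penalized-likelihood confidence interval
#'
#' Locates the two values of a coefficient at which the profile penalized
#' log-likelihood (maximized over all other coefficients, with the Jeffreys
#' penalty always evaluated on the full design) has dropped by
#' \eqn{\chi^2_1(\mathrm{level})/2} from its maximum. Endpoints are found by
#' monotone bisection on the coefficient scale.
#'
#' @inheritParams fit_firth
#' @param fit a converged [fit_firth()] result for `X`, `y`.
#' @param index column index of the coefficient of interest.
#' @param level confidence level in (0, 1).
#' @param beta_tol bisection tolerance on the coefficient scale.
#' @return numeric vector `c(lower, upper)` on the log-odds scale.
#' @export
profile_ci <- function(X, y, fit, index, level = 0.95, weights = NULL,
                       beta_tol = 1e-6) {
  stopifnot(inherits(fit, "firth_fit"), level > 0, level < 1)
  if (!fit$converged) stop("profile_ci requires a converged fit")
  X <- .validate_design(X, y)
  if (is.null(weights)) weights <- rep(1, nrow(X))
  target <- fit$loglik_pen - qchisq(level, 1) / 2
  bhat <- unname(fit$beta[index])
  step0 <- max(unname(fit$se[index]), 1e-2)
  if (!is.finite(step0)) step0 <- 1

  find_endpoint <- function(direction) {
    beta_run <- unname(fit$beta)
    inner <- bhat
    f_inner <- fit$loglik_pen
    step <- step0
    outer <- inner
    repeat {
      outer <- outer + direction * step
      pr <- .profile_loglik(X, y, weights, index, outer, beta_run)
      beta_run <- pr$beta
      if (pr$loglik < target) break
      inner <- outer
      f_inner <- pr$loglik
      step <- step * 1.6
      if (abs(outer - bhat) > 500) stop("profile endpoint search diverged")
    }
    a <- inner  # profile loglik >= target here
    b <- outer  # profile loglik <  target here
    while (abs(b - a) > beta_tol) {
      mid <- (a + b) / 2
      pr <- .profile_loglik(X, y, weights, index, mid, beta_run)
      beta_run <- pr$beta
      if (pr$loglik >= target) a <- mid else b <- mid
    }
    (a + b) / 2
  }

  c(lower = find_endpoint(-1), upper = find_endpoint(+1))
}

#' Penalized likelihood-ratio test for one coefficient
#'
#' Two-tailed test of a single coefficient: the full Firth fit is compared
#' with a fit in which that coefficient is constrained to zero while all
#' other coefficients are re-estimated (the Jeffreys penalty is evaluated on
#' the full-design information in both fits, so the statistic agrees with the
#' profile-likelihood machinery at interval endpoints).
#'
#' @inheritParams profile_ci
#' @param fit optional pre-computed full fit.
#' @return list with `p`, `stat` (the LRT statistic), `fit` (full model
#'   fit) and `fit_null`.
#' @export
penalized_lr_test <- function(X, y, index, weights = NULL, fit = NULL,
                              max_iter = 100L, tol = 1e-8) {
  X <- .validate_design(X, y)
  if (is.null(weights)) weights <- rep(1, nrow(X))
  if (is.null(fit)) fit <- fit_firth(X, y, max_iter, tol, weights)
  beta0 <- unname(fit$beta)
  pr <- .profile_loglik(X, y, weights, index, 0, beta0, max_iter, tol)
  stat <- max(0, 2 * (fit$loglik_pen - pr$loglik))
  list(p = pchisq(stat, df = 1, lower.tail = FALSE), stat = stat,
       fit = fit, fit_null = pr)
}

# Unvalidated fast path used by the scans: penalized LRT for one column
# with warm starts (validation is done once per scan, not per variant).
.firth_lrt_core <- function(X, y, index, init = NULL, weights = NULL,
                            max_iter = 100L, tol = 1e-8) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(init)) init <- numeric(p)
  full <- firth_fit_engine(X, as.numeric(y), as.numeric(weights),
                           seq_len(p) - 1L, as.numeric(init),
                           as.integer(max_iter), tol, 25L, 5.0)
  init0 <- drop(full$beta); init0[index] <- 0
  cons <- firth_fit_engine(X, as.numeric(y), as.numeric(weights),
                           setdiff(seq_len(p), index) - 1L,
                           as.numeric(init0),
                           as.integer(max_iter), tol, 25L, 5.0)
  stat <- max(0, 2 * (full$loglik_pen - cons$loglik_pen))
  fit <- list(beta = setNames(drop(full$beta), colnames(X)),
              se = setNames(drop(full$se), colnames(X)),
              hat = drop(full$hat), loglik_pen = full$loglik_pen,
              converged = full$converged, n_iter = full$n_iter, n = n)
  class(fit) <- "firth_fit"
  list(p = pchisq(stat, df = 1, lower.tail = FALSE), stat = stat, fit = fit)
}

#' Cauchy (ACAT) combination of p-values
#'
#' Combines possibly dependent p-values through the Cauchy tangent
#' transform: \eqn{T = \sum_i w_i \tan\{(0.5 - p_i)\pi\} / \sum_i w_i} and
#' \eqn{p = 0.5 - \arctan(T)/\pi}. Inputs at or above `1 - 1e-15` are
#' clipped; inputs below `1e-15` use the numerically stable tail form
#' \eqn{1/(p_i \pi)}.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @param weights optional nonnegative weights (default equal); must have a
#'   positive sum.
#' @return combined p-value.
#' @examples
#' acat_combine(c(0.01, 0.04))
#' @export
acat_combine <- function(pvals, weights = NULL) {
  if (length(pvals) == 0L) stop("at least one p-value is required")
  if (anyNA(pvals) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]")
  if (is.null(weights)) weights <- rep(1, length(pvals))
  if (length(weights) != length(pvals)) stop("weights length mismatch")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (sum(weights) <= 0) stop("weights must have a positive sum")
  p <- pmin(pvals, 1 - 1e-15)
  term <- ifelse(p < 1e-15, 1 / (p * pi), tan((0.5 - p) * pi))
  t_stat <- sum(weights * term) / sum(weights)
  p_out <- 0.5 - atan(t_stat) / pi
  min(max(p_out, .Machine$double.xmin), 1)
}
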