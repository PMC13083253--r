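# Replication-stage machinery: effective-sample-size-weighted Stouffer
# meta-analysis, winner's-curse effect-size correction, and
# simulation-based replication power.

#' Effective sample size of an unbalanced case-control study
#'
#' \eqn{n_{eff} = 4 / (1/n_{cases} + 1/n_{controls})}: the size of the
#' balanced study with equivalent information, the weight base for
#' sample-size-weighted meta-analysis.
#'
#' @param n_cases,n_controls positive sample counts.
#' @return effective sample size.
#' @examples
#' effective_sample_size(13138, 69775)  # ~44,226
#' @export
effective_sample_size <- function(n_cases, n_controls) {
  stopifnot(all(n_cases > 0), all(n_controls > 0))
  4 / (1 / n_cases + 1 / n_controls)
}

#' Sample-size-weighted Stouffer meta-analysis
#'
#' Converts each study's two-tailed p-value and effect direction to a
#' signed z-score \eqn{z_i = d_i \Phi^{-1}(1 - p_i/2)}, combines with
#' weights \eqn{w_i = \sqrt{n_{eff,i}}} as
#' \eqn{z = \sum w_i z_i / \sqrt{\sum w_i^2}}, and returns the two-tailed
#' meta p-value.
#'
#' @param studies data frame with columns `p` (two-tailed, in (0,1]),
#'   `direction` (+1/-1), and either `neff` or both `n_cases` and
#'   `n_controls`.
#' @return list with `z` and `p`.
#' @export
stouffer_meta <- function(studies) {
  stopifnot(nrow(studies) >= 1L)
  if (any(studies$p <= 0)) stop("p-values must be positive and finite")
  if (any(studies$p > 1)) stop("p-values must lie in (0, 1]")
  if (is.null(studies$neff))
    studies$neff <- effective_sample_size(studies$n_cases,
                                          studies$n_controls)
  d <- sign(studies$direction)
  if (any(d == 0)) {
    warning("direction 0 treated as positive")
    d[d == 0] <- 1
  }
  z_i <- d * qnorm(studies$p / 2, lower.tail = FALSE)
  w <- sqrt(studies$neff)
  z <- sum(w * z_i) / sqrt(sum(w^2))
  list(z = z, p = 2 * pnorm(abs(z), lower.tail = FALSE))
}

#' Winner's-curse correction of a selected effect estimate
#'
#' An effect reaching a stringent significance threshold is biased away
#' from zero because only upward-fluctuating estimates are observed. The
#' correction inverts the selection-conditional mean by parametric
#' bootstrap: for a candidate underlying effect \eqn{\mu}, replicates are
#' drawn from the normal sampling distribution truncated to the selection
#' region \eqn{|\hat\beta| > z_c \cdot se}, and \eqn{\mu} is solved (by
#' monotone bisection with common random numbers) so that the conditional
#' mean of selected replicates equals the observed estimate. The adjusted
#' estimate is shrunk toward zero, never past it.
#'
#' @param beta observed (selected) effect estimate.
#' @param se its standard error (> 0).
#' @param selection_p two-tailed p-value threshold that defined selection.
#' @param B bootstrap replicates per candidate effect.
#' @param seed RNG seed.
#' @param tol bisection tolerance as a fraction of `se`.
#' @return adjusted beta (same sign as `beta`, magnitude in
#'   `[0, |beta|]`).
#' @export
winners_curse_adjust <- function(beta, se, selection_p = 5e-8, B = 2000L,
                                 seed = 1L, tol = 1e-4) {
  stopifnot(se > 0, selection_p > 0, selection_p < 1, B >= 1L)
  zc <- qnorm(selection_p / 2, lower.tail = FALSE)
  c_abs <- zc * se
  b_abs <- abs(beta)
  u <- .run_seeded(seed, runif(B))

  # mean of N(mu, se^2) truncated to |x| > c_abs, via inverse-CDF sampling
  cond_mean <- function(mu) {
    q_hi <- pnorm((c_abs - mu) / se, lower.tail = FALSE)   # upper tail mass
    q_lo <- pnorm((-c_abs - mu) / se)                      # lower tail mass
    q <- q_hi + q_lo
    if (q <= 0 || !is.finite(q)) return(NA_real_)
    # inverse CDF over the two-tail selection region
    uu <- u * q
    x <- ifelse(uu < q_lo,
                mu + se * qnorm(uu),
                mu + se * qnorm(pmax(q - uu, 1e-300), lower.tail = FALSE))
    if (any(!is.finite(x))) return(NA_real_)
    mean(x)
  }

  if (is.na(cond_mean(b_abs))) {
    warning("selection probability underflows; returning unadjusted beta")
    return(beta)
  }
  if (se < 1e-12 * max(1, b_abs)) return(beta)
  # solve cond_mean(mu) = b_abs for mu in [0, b_abs]
  if (cond_mean(0) >= b_abs) return(0 * beta)
  lo <- 0; hi <- b_abs
  while (hi - lo > tol * se) {
    mid <- (lo + hi) / 2
    m <- cond_mean(mid)
    if (is.na(m)) { lo <- mid; next }
    if (m < b_abs) lo <- mid else hi <- mid
  }
  sign(beta) * (lo + hi) / 2
}

#' Simulation-based replication power for a single variant
#'
#' Draws case and control genotypes from the binomial distribution at the
#' control MAF and its odds-ratio-shifted case counterpart, tests each
#' simulated dataset with the Firth penalized LRT (no covariates, matching
#' the idealized design), and reports the fraction of simulations
#' significant at `alpha`. Covariate adjustment in a real analysis can
#' reduce realized power below this estimate.
#'
#' @param freq control minor allele frequency in (0, 1).
#' @param odds_ratio per-allele odds ratio (> 0).
#' @param n_cases,n_controls sample sizes per simulation.
#' @param alpha significance level.
#' @param nsim number of simulations.
#' @param seed RNG seed.
#' @return power estimate.
#' @export
replication_power <- function(freq, odds_ratio, n_cases, n_controls,
                              alpha = 0.05, nsim = 10000L, seed = 1L) {
  stopifnot(freq > 0, freq < 1, odds_ratio > 0)
  odds_case <- odds_ratio * freq / (1 - freq)
  p_case <- odds_case / (1 + odds_case)
  .run_seeded(seed, {
    rej <- vapply(seq_len(nsim), function(i) {
      gc <- rbinom(n_cases, 2, p_case)
      g0 <- rbinom(n_controls, 2, freq)
      # collapse to the six genotype-by-status cells; Firth fit on the
      # weighted design is identical to the full-data fit
      cnt <- c(tabulate(gc + 1L, 3L), tabulate(g0 + 1L, 3L))
      if (sum(cnt[c(2, 3, 5, 6)]) == 0L) return(FALSE)  # monomorphic draw
      X <- cbind(`(Intercept)` = 1, dose = c(0, 1, 2, 0, 1, 2))
      y <- c(1, 1, 1, 0, 0, 0)
      keep <- cnt > 0
      p <- penalized_lr_test(X[keep, , drop = FALSE], y[keep],
                             index = 2L, weights = cnt[keep])$p
      p < alpha
    }, NA)
    mean(rej)
  })
}
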