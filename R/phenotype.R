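# Age-at-onset linear regression and right-censored survival models for
# carriers of candidate variants and gene-level URV burdens.

#' Age-at-onset regression
#'
#' Ordinary least squares of age at onset (cases only) on an exposure
#' (minor allele count of a variant, or a gene burden score) adjusted for
#' the supplied covariates (typically sex, cohort indicators, PCs and the
#' rare synonymous count). `B` is the onset shift in years per unit
#' exposure.
#'
#' @param onset numeric onset ages (`NA` excluded).
#' @param exposure numeric exposure vector.
#' @param covariates data frame or matrix of covariates (factors allowed).
#' @return list with `B`, `se`, `p`, `n`.
#' @export
onset_regression <- function(onset, exposure, covariates = NULL) {
  ok <- !is.na(onset) & !is.na(exposure)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    ok <- ok & complete.cases(covariates)
  }
  x <- exposure[ok]
  if (length(unique(x)) < 2L) stop("exposure is constant")
  dat <- data.frame(onset = onset[ok], exposure = x)
  if (!is.null(covariates)) dat <- cbind(dat, covariates[ok, , drop = FALSE])
  fit <- lm(onset ~ ., data = dat)
  sm <- summary(fit)$coefficients
  list(B = unname(sm["exposure", 1]), se = unname(sm["exposure", 2]),
       p = unname(sm["exposure", 4]), n = sum(ok))
}

#' Cox proportional-hazards survival model
#'
#' Partial-likelihood fit (Efron tie handling) of right-censored survival
#' time on an exposure with optional covariates; the p-value is the
#' partial likelihood-ratio test for the exposure.
#'
#' @param time positive survival times.
#' @param event event indicator (1 event, 0 censored).
#' @param exposure numeric exposure vector.
#' @param covariates optional covariate data frame.
#' @return list with `hr` (hazard ratio), `log_hr`, `se`, `p`, `n`,
#'   `n_events`.
#' @export
survival_cox <- function(time, event, exposure, covariates = NULL) {
  ok <- !is.na(time) & !is.na(event) & !is.na(exposure)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    ok <- ok & complete.cases(covariates)
  }
  if (any(time[ok] <= 0)) stop("survival times must be positive")
  if (sum(event[ok]) == 0L) stop("no events observed")
  if (length(unique(exposure[ok])) < 2L) stop("exposure is constant")
  dat <- data.frame(time = time[ok], event = event[ok],
                    exposure = exposure[ok])
  if (!is.null(covariates)) dat <- cbind(dat, covariates[ok, , drop = FALSE])
  fit <- survival::coxph(survival::Surv(time, event) ~ ., data = dat,
                         ties = "efron")
  fit0 <- if (ncol(dat) > 3L)
    survival::coxph(survival::Surv(time, event) ~ . - exposure, data = dat,
                    ties = "efron")
  else NULL
  ll1 <- fit$loglik[2]
  ll0 <- if (is.null(fit0)) fit$loglik[1] else fit0$loglik[2]
  stat <- max(0, 2 * (ll1 - ll0))
  cf <- summary(fit)$coefficients["exposure", ]
  list(hr = unname(cf["exp(coef)"]), log_hr = unname(cf["coef"]),
       se = unname(cf["se(coef)"]),
       p = pchisq(stat, df = 1, lower.tail = FALSE),
       n = sum(ok), n_events = sum(event[ok]))
}

#' Kaplan-Meier median survival difference between carriers and non-carriers
#'
#' Difference in median Kaplan-Meier survival (carriers minus
#' non-carriers), one summary of a survival shift on the time scale. The
#' median is undefined when the survival curve never crosses 0.5.
#'
#' @param time,event as in [survival_cox()].
#' @param carrier logical carrier indicator.
#' @return list with `median_carrier`, `median_noncarrier`,
#'   `delta_median`.
#' @export
km_median_difference <- function(time, event, carrier) {
  ok <- !is.na(time) & !is.na(event) & !is.na(carrier)
  sf <- survival::survfit(survival::Surv(time[ok], event[ok]) ~ carrier[ok])
  med <- summary(sf)$table[, "median"]
  m0 <- unname(med[grep("FALSE", names(med))])
  m1 <- unname(med[grep("TRUE", names(med))])
  list(median_carrier = m1, median_noncarrier = m0,
       delta_median = m1 - m0)
}
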