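# Exome-wide and targeted rare single-variant association scans:
# per-variant Firth penalized-LRT tests within a MAF window, with
# inflation diagnostics, Bonferroni thresholds and post-hoc screens.

.scan_one_variant <- function(g, hemi, y, covars, maf_window, ci, level,
                              warm = NULL, ci_tol = 1e-6) {
  ok <- !is.na(g)
  res <- list(mac_case = NA_integer_, mac_control = NA_integer_,
              freq_case = NA_real_, freq_control = NA_real_,
              beta = NA_real_, or_ = NA_real_, ci_lo = NA_real_,
              ci_hi = NA_real_, p = NA_real_, n_used = sum(ok),
              status = "failed")
  if (sum(ok) == 0L) { res$status <- "monomorphic"; return(res) }
  g <- g[ok]; yv <- y[ok]; hv <- hemi[ok]
  # orient to the minor allele
  af_all <- allele_freq(g, hv)
  if (!is.na(af_all$freq) && af_all$freq > 0.5) {
    g <- ifelse(hv, 1L - g, 2L - g)
    af_all <- allele_freq(g, hv)
  }
  fc <- allele_freq(g[yv == 1], hv[yv == 1])
  f0 <- allele_freq(g[yv == 0], hv[yv == 0])
  res$mac_case <- fc$mac; res$mac_control <- f0$mac
  res$freq_case <- fc$freq; res$freq_control <- f0$freq
  if (af_all$mac == 0L) { res$status <- "monomorphic"; return(res) }
  if (!is.null(maf_window) &&
      (af_all$freq <= maf_window[1] || af_all$freq >= maf_window[2])) {
    res$status <- "out_of_window"; return(res)
  }
  X <- cbind(`(Intercept)` = 1, dose = g, covars[ok, , drop = FALSE])
  init <- if (is.null(warm)) NULL else c(warm[1L], 0, warm[-1L])
  out <- tryCatch({
    lrt <- .firth_lrt_core(X, yv, index = 2L, init = init)
    res$beta <- unname(lrt$fit$beta[2L])
    res$or_ <- exp(res$beta)
    res$p <- lrt$p
    if (ci) {
      iv <- profile_ci(X, yv, lrt$fit, index = 2L, level = level,
                       beta_tol = ci_tol)
      res$ci_lo <- exp(iv[["lower"]]); res$ci_hi <- exp(iv[["upper"]])
    }
    res$status <- "tested"
    res
  }, error = function(e) { res$status <- "failed"; res })
  out
}

#' Rare single-variant association scan
#'
#' Tests every variant of qualifying impact whose minor allele frequency
#' (over all used samples, non-missing denominator, hemizygous males
#' contributing one allele) falls strictly inside `maf_window`, using the
#' Firth penalized likelihood-ratio test of case status on dosage,
#' adjusted for sex, the leading PCs and the per-sample rare synonymous
#' count. Samples with missing genotype at a variant are dropped for that
#' test only; samples with incomplete covariates are dropped globally and
#' counted. Monomorphic and out-of-window variants are reported with a
#' status, never silently skipped.
#'
#' @param G samples x variants dosage matrix.
#' @param samples sample table (`phenotype` 1/2, `sex`, PCs, `syn_count`).
#' @param variants variant table (`variant_id`, `chrom`, `gene`, `impact`).
#' @param maf_window open MAF interval `(lo, hi)` for testable variants.
#' @param impact_filter impact classes to test.
#' @param n_pcs number of PCs to adjust for.
#' @param ci compute profile penalized-likelihood confidence intervals
#'   (slower; off by default for large scans).
#' @param level CI level.
#' @param ci_tol bisection tolerance for CI endpoints (coefficient scale).
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @return list with `results` (one row per candidate variant) and
#'   `summary` (`n_tests`, `bonferroni`, `lambda_1000`, `n_dropped_covar`).
#' @export
single_variant_scan <- function(G, samples, variants,
                                maf_window = c(5e-5, 0.05),
                                impact_filter = c("HIGH", "MODERATE"),
                                n_pcs = 10, ci = FALSE, level = 0.95,
                                alpha = 0.05, ci_tol = 1e-6) {
  stopifnot(ncol(G) == nrow(variants), nrow(G) == nrow(samples))
  keep_v <- variants$impact %in% impact_filter
  if (!any(keep_v)) {
    warning("no variants of the requested impact classes")
    return(list(results = data.frame(), summary = list(
      n_tests = 0L, bonferroni = NA_real_, lambda_1000 = NA_real_,
      n_dropped_covar = 0L)))
  }
  covars <- covariate_matrix(samples, n_pcs = n_pcs)
  ok_cov <- complete.cases(covars) & !is.na(samples$phenotype)
  n_dropped <- sum(!ok_cov)
  y <- as.numeric(samples$phenotype == 2L)[ok_cov]
  covars <- covars[ok_cov, , drop = FALSE]
  Gs <- G[ok_cov, keep_v, drop = FALSE]
  vs <- variants[keep_v, , drop = FALSE]
  hemi_all <- (samples$sex == 1L)[ok_cov]

  # covariate-only warm start shared by every per-variant fit
  X0 <- .validate_design(cbind(`(Intercept)` = 1, covars), y)
  warm <- unname(fit_firth(X0, y)$beta)

  rows <- lapply(seq_len(nrow(vs)), function(v) {
    hemi <- if (vs$chrom[v] == "X") hemi_all else rep(FALSE, length(y))
    .scan_one_variant(Gs[, v], hemi, y, covars, maf_window, ci, level, warm,
                      ci_tol)
  })
  results <- cbind(vs[, intersect(c("variant_id", "chrom", "pos", "ref",
                                    "alt", "gene", "impact"), names(vs)),
                      drop = FALSE],
                   do.call(rbind, lapply(rows, as.data.frame)))
  rownames(results) <- NULL
  tested <- results$status == "tested"
  n_tests <- sum(tested)
  if (n_tests == 0L)
    warning("no variants inside the MAF window were testable")
  lam <- if (n_tests >= 1L)
    suppressWarnings(genomic_inflation(results$p[tested],
                                       sum(y == 1), sum(y == 0))$lambda_1000)
  else NA_real_
  list(results = results,
       summary = list(n_tests = n_tests,
                      bonferroni = if (n_tests >= 1L)
                        bonferroni_threshold(n_tests, alpha) else NA_real_,
                      lambda_1000 = lam, n_dropped_covar = n_dropped))
}

#' Targeted scan of curated gene panels
#'
#' Restricts the single-variant scan to variants in the listed genes. The
#' per-supercohort call-rate flag is deliberately ignored here (panel genes
#' with subpar call rates in some subcohorts are still assessed); all other
#' QC flags in `qc_report` still exclude variants. The Bonferroni threshold
#' is computed over the tested panel variants only.
#'
#' @inheritParams single_variant_scan
#' @param gene_list nonempty character vector of panel genes.
#' @param qc_report optional [variant_qc_mask()] result.
#' @export
targeted_scan <- function(G, samples, variants, gene_list,
                          qc_report = NULL, maf_window = c(5e-5, 0.05),
                          impact_filter = c("HIGH", "MODERATE"),
                          n_pcs = 10, ci = FALSE, level = 0.95,
                          alpha = 0.05) {
  stopifnot(length(gene_list) >= 1L)
  keep <- variants$gene %in% gene_list
  if (!is.null(qc_report)) {
    qr <- qc_report[match(variants$variant_id, qc_report$variant_id), ]
    other_fail <- qr$hwe_fail | qr$length_fail | qr$spanning_del_fail |
      qr$batch_fail
    keep <- keep & !ifelse(is.na(other_fail), FALSE, other_fail)
  }
  if (!any(keep)) {
    warning("no variants in the requested genes")
    return(list(results = data.frame(), summary = list(
      n_tests = 0L, bonferroni = NA_real_, lambda_1000 = NA_real_,
      n_dropped_covar = 0L)))
  }
  single_variant_scan(G[, keep, drop = FALSE], samples,
                      variants[keep, , drop = FALSE], maf_window,
                      impact_filter, n_pcs, ci, level, alpha)
}

#' Cochran heterogeneity test for two effect estimates
#'
#' Fixed-effect inverse-variance Q statistic for two studies, reducing to
#' \eqn{Q = (\beta_1 - \beta_2)^2 / (se_1^2 + se_2^2)} with a chi-square
#' (1 df) p-value. Used as a post-hoc screen comparing scan estimates to
#' external study estimates.
#'
#' @param beta1,se1,beta2,se2 estimates and standard errors.
#' @return list with `q` and `p`.
#' @export
heterogeneity_test <- function(beta1, se1, beta2, se2) {
  stopifnot(se1 > 0, se2 > 0)
  q <- (beta1 - beta2)^2 / (se1^2 + se2^2)
  list(q = q, p = pchisq(q, df = 1, lower.tail = FALSE))
}

#' Case-case batch screen for candidate variants
#'
#' Reuses the control-control machinery among case cohorts; a candidate
#' fails the screen when its minimum case-case p-value is smaller than its
#' case-control association p-value (batch structure explains the signal
#' better than phenotype).
#'
#' @param G samples x variants dosage matrix (candidate variants).
#' @param samples sample table.
#' @param assoc_p per-variant case-control association p-values.
#' @param n_pcs,min_cohort_size as in [control_control_scan()].
#' @return data frame `variant_id`, `min_p_case_case`, `p_assoc`, `fail`.
#' @export
case_case_screen <- function(G, samples, assoc_p, n_pcs = 4,
                             min_cohort_size = 100) {
  cases <- samples$phenotype == 2L
  sm <- samples[cases, , drop = FALSE]
  sm$phenotype <- 1L  # reuse the control-control scanner on cases
  cc <- control_control_scan(G[cases, , drop = FALSE], sm, n_pcs,
                             min_cohort_size)
  data.frame(variant_id = cc$variant_id, min_p_case_case = cc$min_p,
             p_assoc = assoc_p,
             fail = !is.na(cc$min_p) & cc$min_p < assoc_p)
}
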